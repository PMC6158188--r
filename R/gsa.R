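# Directional gene-set analysis and over-representation tests.
#
# The set statistic is the mean of gene-level values; five directionality
# classes are scored against a size-matched gene-sampling null (genes
# drawn without replacement from the analysed background):
#   non-directional      mean |t|          — magnitude only
#   distinct-dir up/down mean t            — coherent shift (one-sided each way)
#   mixed-dir up/down    mean |t| over the up- (down-) regulated subset
#                        of the set, scored separately
# Gene sampling (rather than sample permutation) is used because two
# replicates per phase make sample permutation degenerate.

#' Directional gene-set analysis
#'
#' @param stats An `fx_gene_stats` data frame (see [differential_stats()])
#'   or a named numeric vector of gene-level t statistics.
#' @param sets Named list: set id -> character vector of gene ids.
#' @param n_perm Number of null draws (>= 1000 recommended).
#' @param seed RNG seed for the null draws.
#' @param min_coverage Minimum fraction of a set's genes that must be
#'   present in `stats` (warns below, skips empty sets with a notice).
#' @return Data frame of class `fx_gsa`: per set, its analysed size and
#'   empirical p-values `p_dist_up, p_dist_dn, p_mix_up, p_mix_dn,
#'   p_nondir` with matching BH-adjusted `q_` columns. Empirical p =
#'   `(1 + #{null >= observed}) / (n_perm + 1)`.
#' @export
gene_set_analysis <- function(stats, sets, n_perm = 1999, seed = 1,
                              min_coverage = 0.8) {
  t_all <- if (inherits(stats, "fx_gene_stats"))
    setNames(stats$t, stats$gene) else stats
  assert(is.numeric(t_all) && !is.null(names(t_all)),
         "stats must be gene-level statistics with gene names")
  assert(n_perm >= 1, "n_perm must be >= 1")

  mapped <- lapply(sets, function(g) intersect(g, names(t_all)))
  cov <- mapply(function(m, g) length(m) / max(1L, length(g)), mapped, sets)
  empty <- lengths(mapped) == 0L
  if (any(empty))
    message("skipping empty gene sets after mapping: ",
            paste(names(sets)[empty], collapse = ", "))
  low <- !empty & cov < min_coverage
  if (any(low))
    warning("gene sets with < ", min_coverage * 100, "% coverage: ",
            paste(names(sets)[low], collapse = ", "), call. = FALSE)
  mapped <- mapped[!empty]
  if (!length(mapped))
    return(structure(data.frame(), class = c("fx_gsa", "data.frame")))

  # mean over an empty subset is defined as 0 so that an all-zero input
  # gives p = 1 in every class
  mean0 <- function(x) if (length(x)) mean(x) else 0
  set_stats <- function(tv) {
    c(dist = mean(tv),
      mix_up = mean0(tv[tv > 0]),
      mix_dn = mean0(abs(tv[tv < 0])),
      nondir = mean(abs(tv)))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  sizes <- lengths(mapped)
  null_by_size <- new.env(parent = emptyenv())
  null_stats <- function(s) {
    key <- as.character(s)
    if (!is.null(null_by_size[[key]])) return(null_by_size[[key]])
    # size-matched draws without replacement from the analysed background
    idx <- vapply(seq_len(n_perm),
                  function(i) sample.int(length(t_all), s), integer(s))
    draws <- matrix(t_all[idx], nrow = n_perm, byrow = TRUE)
    pos <- draws > 0
    neg <- draws < 0
    ns <- cbind(dist = rowMeans(draws),
                mix_up = ifelse(rowSums(pos) > 0,
                                rowSums(draws * pos) / rowSums(pos), 0),
                mix_dn = ifelse(rowSums(neg) > 0,
                                rowSums(-draws * neg) / rowSums(neg), 0),
                nondir = rowMeans(abs(draws)))
    null_by_size[[key]] <- ns
    ns
  }

  emp_p <- function(null, obs, lower = FALSE) {
    hits <- if (lower) sum(null <= obs) else sum(null >= obs)
    (1 + hits) / (length(null) + 1)
  }

  rows <- lapply(names(mapped), function(sid) {
    tv <- t_all[mapped[[sid]]]
    obs <- set_stats(tv)
    nl <- null_stats(length(tv))
    data.frame(set = sid, size = length(tv),
               stat_dist = obs[["dist"]], stat_nondir = obs[["nondir"]],
               p_dist_up = emp_p(nl[, "dist"], obs[["dist"]]),
               p_dist_dn = emp_p(nl[, "dist"], obs[["dist"]], lower = TRUE),
               p_mix_up = emp_p(nl[, "mix_up"], obs[["mix_up"]]),
               p_mix_dn = emp_p(nl[, "mix_dn"], obs[["mix_dn"]]),
               p_nondir = emp_p(nl[, "nondir"], obs[["nondir"]]))
  })
  out <- do.call(rbind, rows)
  for (cl in c("p_dist_up", "p_dist_dn", "p_mix_up", "p_mix_dn", "p_nondir"))
    out[[sub("^p_", "q_", cl)]] <- bh_adjust(out[[cl]])
  structure(out, class = c("fx_gsa", "data.frame"))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided exact tail `P(X >= overlap)` for each set, with the
#' hypergeometric distribution on (set size in universe, universe size,
#' selection size). No normal approximation.
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param universe Character vector, the analysed background.
#' @param sets Named list of gene sets.
#' @return Data frame: set, set_size (in universe), overlap, p_value,
#'   q_value (BH).
#' @export
ora_hypergeometric <- function(selected, universe, sets) {
  offenders <- setdiff(selected, universe)
  assert(length(offenders) == 0L,
         "selected genes not in universe: ", paste(offenders, collapse = ", "))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(sid) {
    K <- length(intersect(sets[[sid]], universe))
    k <- length(intersect(sets[[sid]], selected))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = sid, set_size = K, overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; a thin, named wrapper over the standard
#' implementation so results tables carry a single convention.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values (same order), `q >= p`, monotone in rank.
#' @export
bh_adjust <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Read / write gene sets in GMT format
#'
#' @param path File path (tab-separated: set id, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene sets.
#' @param descriptions Optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
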