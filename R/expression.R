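# Expression matrices (genes x samples, FPKM), the low-expression filter,
# profile standardization and two-phase differential statistics.

#' Create an expression matrix
#'
#' @param values Genes x samples FPKM matrix (non-negative).
#' @param time_h Per-sample time annotation.
#' @param replicate Per-sample replicate id.
#' @param phase Optional per-sample phase label.
#' @return A list of class `fx_expr`.
#' @export
expression_matrix <- function(values, time_h, replicate = seq_len(ncol(values)),
                              phase = NULL) {
  values <- as.matrix(values)
  assert(all(values >= 0), "FPKM values must be non-negative")
  assert(length(unique(time_h)) >= 2L, "need at least 2 time points")
  assert(length(time_h) == ncol(values), "time_h must annotate every sample")
  reps_per_tp <- table(time_h)
  if (any(reps_per_tp < 2))
    warning("time points with a single replicate: ",
            paste(names(reps_per_tp)[reps_per_tp < 2], collapse = ", "),
            " (replicated sampling is the intended design)", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  structure(list(values = values,
                 samples = data.frame(sample = colnames(values),
                                      time_h = time_h, replicate = replicate,
                                      phase = phase %||% NA_character_)),
            class = "fx_expr")
}

timepoint_means <- function(mat) {
  tps <- sort(unique(mat$samples$time_h))
  out <- sapply(tps, function(tp)
    rowMeans(mat$values[, mat$samples$time_h == tp, drop = FALSE]))
  colnames(out) <- paste0("t", tps)
  attr(out, "time_h") <- tps
  out
}

#' Remove genes with little or no expression
#'
#' A gene is removed iff its replicate-mean FPKM falls below
#' `fpkm_threshold` at `min_low_timepoints` or more time points —
#' the screen applied before time-course clustering.
#'
#' @param mat An `fx_expr`.
#' @param fpkm_threshold FPKM level under which a time point counts as
#'   "little expression" (default 1).
#' @param min_low_timepoints Number of low time points that triggers
#'   removal (default 2).
#' @return A filtered `fx_expr`; removed ids in `attr(, "removed")`.
#' @export
filter_low_expression <- function(mat, fpkm_threshold = 1,
                                  min_low_timepoints = 2) {
  assert(fpkm_threshold >= 0, "fpkm_threshold must be >= 0")
  tm <- timepoint_means(mat)
  low_count <- rowSums(tm < fpkm_threshold)
  keep <- low_count < min_low_timepoints
  out <- mat
  out$values <- mat$values[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(mat$values)[!keep]
  out
}

#' Standardize time-course profiles
#'
#' Collapses replicates to per-time-point means and z-scores each gene
#' across time points (mean 0, sd 1) — the scale on which profile shapes,
#' not expression levels, are compared. Zero-variance genes are dropped
#' with a notice.
#'
#' @param mat A filtered `fx_expr`.
#' @return Genes x time-points matrix; dropped ids in `attr(, "dropped")`,
#'   time grid in `attr(, "time_h")`.
#' @export
standardize_profiles <- function(mat) {
  tm <- timepoint_means(mat)
  sds <- apply(tm, 1, sd)
  dropped <- rownames(tm)[sds == 0]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance gene(s)")
  tm <- tm[sds > 0, , drop = FALSE]
  Z <- (tm - rowMeans(tm)) / apply(tm, 1, sd)
  attr(Z, "dropped") <- dropped
  attr(Z, "time_h") <- attr(tm, "time_h")
  Z
}

#' Two-phase differential statistics
#'
#' Per gene: log2 fold change between the phase means on the FPKM+1
#' scale, and a Welch (unequal-variance) t-test across replicates on
#' log2(FPKM+1).
#'
#' @param mat An `fx_expr` with phase labels (or use `time_h` values as
#'   phases via `phase_a`/`phase_b` matching `samples$phase`).
#' @param phase_a,phase_b Phase labels to contrast (B vs A).
#' @return A data frame of class `fx_gene_stats`: gene, log2fc, t, df,
#'   p_value, direction.
#' @export
differential_stats <- function(mat, phase_a, phase_b) {
  ia <- which(mat$samples$phase == phase_a)
  ib <- which(mat$samples$phase == phase_b)
  assert(length(ia) >= 1 && length(ib) >= 1,
         "phases not found in sample annotation: ",
         paste(setdiff(c(phase_a, phase_b), mat$samples$phase), collapse = ", "))
  A <- mat$values[, ia, drop = FALSE]
  B <- mat$values[, ib, drop = FALSE]
  log2fc <- log2((rowMeans(B) + 1) / (rowMeans(A) + 1))
  if (length(ia) < 2 || length(ib) < 2) {
    warning("single replicate in a phase: fold changes only, no p-values",
            call. = FALSE)
    out <- data.frame(gene = rownames(A), log2fc = log2fc, t = NA_real_,
                      df = NA_real_, p_value = NA_real_,
                      direction = sign(log2fc))
    class(out) <- c("fx_gene_stats", "data.frame")
    return(out)
  }
  la <- log2(A + 1); lb <- log2(B + 1)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  na <- length(ia); nb <- length(ib)
  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, (mb - ma) / sqrt(se2),
               ifelse(mb == ma, 0, sign(mb - ma) * Inf))
  dfree <- ifelse(se2 > 0,
                  se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                  na + nb - 2)
  p <- 2 * pt(-abs(tt), dfree)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)   # keep p in (0, 1]
  tt[!is.finite(tt)] <- sign(tt[!is.finite(tt)]) * 1e6
  out <- data.frame(gene = rownames(A), log2fc = log2fc, t = tt, df = dfree,
                    p_value = p, direction = sign(log2fc))
  class(out) <- c("fx_gene_stats", "data.frame")
  out
}

#' Annotate clusters with a gene list
#'
#' Generic cross-tabulation of a hard cluster assignment against an
#' externally supplied gene list (e.g. annotated transcription factors).
#'
#' @param clustering An `fx_fcm` (see [fuzzy_cmeans()]).
#' @param gene_list Character vector of gene ids of interest.
#' @return Data frame: cluster, n_genes, n_in_list, members (comma-joined).
#' @export
annotate_clusters <- function(clustering, gene_list) {
  hard <- clustering$assignment
  hard <- hard[!is.na(hard)]
  do.call(rbind, lapply(sort(unique(hard)), function(k) {
    genes <- names(hard)[hard == k]
    hits <- intersect(genes, gene_list)
    data.frame(cluster = k, n_genes = length(genes), n_in_list = length(hits),
               members = paste(hits, collapse = ","))
  }))
}

#' Read / write an expression matrix with its sample sheet
#'
#' The matrix is a TSV (first column `gene`, one column per sample); the
#' sample sheet is a TSV with columns `sample, time_h, replicate, phase`.
#'
#' @param path Matrix file path.
#' @param sample_sheet Sample-sheet file path.
#' @return An `fx_expr`.
#' @export
read_expression <- function(path, sample_sheet) {
  vals <- read.delim(path, check.names = FALSE)
  genes <- vals[[1]]
  vals <- as.matrix(vals[, -1, drop = FALSE])
  rownames(vals) <- genes
  ss <- read.delim(sample_sheet)
  assert(all(colnames(vals) %in% ss$sample),
         "samples missing from sheet: ",
         paste(setdiff(colnames(vals), ss$sample), collapse = ", "))
  ss <- ss[match(colnames(vals), ss$sample), ]
  expression_matrix(vals, time_h = ss$time_h, replicate = ss$replicate,
                    phase = if ("phase" %in% names(ss)) ss$phase else NULL)
}

#' @rdname read_expression
#' @param mat An `fx_expr`.
#' @export
write_expression <- function(mat, path, sample_sheet) {
  tab <- data.frame(gene = rownames(mat$values), mat$values,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mat$samples, sample_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
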