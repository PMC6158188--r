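# Metabolite pool-size tables (metabolites x samples, umol/gDCW) and the
# unsupervised side of the metabolomics screen: preprocessing, PCA, and
# the hierarchical row/column ordering used for heatmaps.

#' Create a metabolite pool-size table
#'
#' @param values Numeric matrix, metabolites x samples (umol/gDCW);
#'   missing measurements as `NA`.
#' @param time_h Per-sample time annotation (h).
#' @param replicate Per-sample replicate id.
#' @param metabolite_ids Row ids (defaults to rownames).
#' @return A list of class `fx_pool_table`.
#' @export
pool_table <- function(values, time_h, replicate = seq_len(ncol(values)),
                       metabolite_ids = rownames(values)) {
  values <- as.matrix(values)
  assert(ncol(values) >= 2L, "need at least 2 samples")
  assert(length(time_h) == ncol(values), "time_h must annotate every sample")
  assert(all(values >= 0, na.rm = TRUE), "pool sizes must be non-negative")
  if (is.null(metabolite_ids))
    metabolite_ids <- paste0("met", seq_len(nrow(values)))
  rownames(values) <- metabolite_ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  structure(list(values = values,
                 metabolite_ids = metabolite_ids,
                 samples = data.frame(sample = colnames(values),
                                      time_h = time_h,
                                      replicate = replicate)),
            class = "fx_pool_table")
}

#' Preprocess a pool table for PCA/PLS
#'
#' Missing values are imputed by half the metabolite's minimum observed
#' value (the usual limit-of-detection surrogate), then optionally
#' log-transformed, then centered per metabolite and scaled (autoscale =
#' unit variance; pareto = divide by sqrt of the standard deviation).
#' Metabolites that are constant across samples carry no information under
#' autoscaling and are dropped with a warning.
#'
#' @param table An `fx_pool_table`.
#' @param transform `"none"` or `"log"` (natural log; requires positive
#'   values after imputation).
#' @param scale `"autoscale"` or `"pareto"`.
#' @return An `fx_pool_table` with processed values; dropped metabolite
#'   ids in `attr(, "dropped")`.
#' @export
preprocess_pools <- function(table, transform = c("none", "log"),
                             scale = c("autoscale", "pareto")) {
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  X <- table$values
  miss_frac <- rowMeans(is.na(X))
  assert(all(miss_frac < 0.5),
         "metabolites with >= 50% missing values: ",
         paste(rownames(X)[miss_frac >= 0.5], collapse = ", "))
  for (i in which(rowSums(is.na(X)) > 0)) {
    X[i, is.na(X[i, ])] <- min(X[i, ], na.rm = TRUE) / 2
  }
  if (transform == "log") {
    assert(all(X > 0), "log transform requires strictly positive values")
    X <- log(X)
  }
  sds <- apply(X, 1, sd)
  dropped <- character()
  if (any(sds == 0)) {
    dropped <- rownames(X)[sds == 0]
    warning("dropping constant metabolites: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- X - rowMeans(X)
  X <- X / switch(scale, autoscale = sds, pareto = sqrt(sds))
  out <- table
  out$values <- X
  out$metabolite_ids <- rownames(X)
  attr(out, "dropped") <- dropped
  attr(out, "preprocessed") <- TRUE
  out
}

#' Principal component analysis of a pool table
#'
#' Samples are observations, metabolites are variables; the decomposition
#' is the SVD of the (already centered) sample matrix.
#'
#' @param table A preprocessed `fx_pool_table` (no missing values), or a
#'   samples x variables matrix.
#' @param n_components Number of components (truncated to the matrix rank
#'   with a message if larger).
#' @return A list of class `fx_pca`: `scores` (samples x A), `loadings`
#'   (variables x A), `explained_variance_fraction`.
#' @export
run_pca <- function(table, n_components = NULL) {
  X <- if (inherits(table, "fx_pool_table")) t(table$values) else as.matrix(table)
  assert(!anyNA(X), "PCA input contains missing values; preprocess first")
  Xc <- sweep(X, 2, colMeans(X))   # no-op on preprocessed tables
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  rank <- sum(pos)
  A <- n_components %||% rank
  if (A > rank) {
    message("requested ", A, " components but rank is ", rank, "; truncating")
    A <- rank
  }
  scores <- sv$u[, seq_len(A), drop = FALSE] %*% diag(sv$d[seq_len(A)], A)
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(A))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = sv$d[seq_len(A)]^2 / sum(sv$d^2),
                 center = colMeans(X)),
            class = "fx_pca")
}

#' Heatmap leaf orders
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of rows
#' and columns; rows/columns are pre-sorted by id so that distance ties
#' break deterministically.
#'
#' @param table A preprocessed `fx_pool_table` or a plain matrix.
#' @return List with `row_order` and `col_order` (ids in leaf order).
#' @export
heatmap_order <- function(table) {
  X <- if (inherits(table, "fx_pool_table")) table$values else as.matrix(table)
  if (is.null(rownames(X))) rownames(X) <- paste0("r", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  leaf_order <- function(M) {
    M <- M[order(rownames(M)), , drop = FALSE]
    if (nrow(M) == 1L) return(rownames(M))
    hc <- hclust(dist(M, method = "euclidean"), method = "complete")
    rownames(M)[hc$order]
  }
  list(row_order = leaf_order(X), col_order = leaf_order(t(X)))
}

#' Read / write a pool table
#'
#' TSV layout: first column `metabolite`, remaining columns samples; two
#' leading header rows `time_h` and `replicate` annotate the samples.
#'
#' @param path File path.
#' @return An `fx_pool_table`.
#' @export
read_pool_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  assert(all(raw[[1]][1:2] == c("time_h", "replicate")),
         "pool table must start with time_h and replicate annotation rows")
  time_h <- as.numeric(raw[1, -1])
  replicate <- unlist(raw[2, -1], use.names = FALSE)
  vals <- as.matrix(raw[-(1:2), -1, drop = FALSE])
  storage.mode(vals) <- "numeric"
  rownames(vals) <- raw[[1]][-(1:2)]
  pool_table(vals, time_h = time_h, replicate = replicate)
}

#' @rdname read_pool_table
#' @param table An `fx_pool_table`.
#' @export
write_pool_table <- function(table, path) {
  hdr <- rbind(c("time_h", table$samples$time_h),
               c("replicate", table$samples$replicate))
  body <- cbind(rownames(table$values), format(table$values, digits = 12,
                                               trim = TRUE, scientific = FALSE))
  out <- rbind(c("metabolite", colnames(table$values)), hdr, body)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
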