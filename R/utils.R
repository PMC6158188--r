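#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd var prcomp dist hclust as.dendrogram order.dendrogram
#'   phyper p.adjust pt qnorm rnorm rlnorm runif kmeans cor quantile setNames
#'   dhyper aggregate
#' @importFrom utils read.delim write.table head tail modifyList
NULL

abort <- function(..., class = "fluxomix_error") {
  stop(errorCondition(paste0(...), class = c(class, "error")))
}

assert <- function(cond, ..., class = "fluxomix_error") {
  if (!isTRUE(cond)) abort(..., class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a stream seed from a master seed
#'
#' Deterministic arithmetic so one user-facing seed can drive many
#' independent generators without manual bookkeeping.
#' @param seed Master seed (integer).
#' @param offset Stream index.
#' @return A 32-bit-safe integer seed.
#' @export
derive_seed <- function(seed, offset) {
  # double arithmetic stays exact well past 2^31, so chained derivations
  # cannot overflow the 32-bit seed range
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 9973) %% 2147483647)
}
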