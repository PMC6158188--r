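# Fuzzy c-means clustering of standardized expression time courses, in
# the soft-clustering style used for transcript profiles: every gene gets
# a membership in each cluster, and a hard assignment only where its best
# membership is convincing.

#' Fuzzy c-means clustering
#'
#' Alternating updates with Euclidean distance: centers are the
#' membership^m weighted profile means, memberships follow
#' `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))` (so `u_ij` is proportional to
#' `(1/d_ij^2)^(1/(m-1))`), iterated until the largest center shift drops
#' below `tol`. A profile coinciding with a center gets membership 1
#' there. Initial centers are `k` distinct profiles drawn with the given
#' seed, so runs are reproducible.
#'
#' @param profiles Genes x time-points matrix (standardized).
#' @param k Number of clusters (>= 2, <= number of genes).
#' @param m Fuzzifier (> 1); see [estimate_fuzzifier()].
#' @param max_iter Iteration cap; non-convergence is reported, not fatal.
#' @param tol Convergence threshold on the center shift.
#' @param seed RNG seed for center initialization.
#' @param n_init Number of random restarts; the run with the lowest final
#'   objective is returned (restart seeds are derived deterministically
#'   from `seed`).
#' @param min_membership Hard-assignment threshold: a gene is assigned to
#'   its argmax cluster only if that membership reaches this value
#'   (`NA` otherwise) — the usual "alpha core" convention.
#' @return A list of class `fx_fcm`: `memberships` (genes x k, rows sum
#'   to 1), `centers` (k x time points), `assignment`, `converged`,
#'   `iterations`, `objective_trace` (non-increasing).
#' @export
fuzzy_cmeans <- function(profiles, k, m = 1.25, max_iter = 200, tol = 1e-6,
                         seed = 1, n_init = 5, min_membership = 0.7) {
  if (n_init > 1) {
    runs <- lapply(seq_len(n_init), function(i)
      fuzzy_cmeans(profiles, k, m, max_iter, tol,
                   seed = derive_seed(seed, i), n_init = 1,
                   min_membership = min_membership))
    best <- which.min(vapply(runs, function(r) tail(r$objective_trace, 1), 0))
    out <- runs[[best]]
    out$seed <- seed
    return(out)
  }
  X <- as.matrix(profiles)
  n <- nrow(X)
  assert(k >= 2, "k must be >= 2")
  assert(k <= n, "k (", k, ") exceeds the number of genes (", n, ")")
  assert(m > 1, "fuzzifier m must be > 1")
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(n))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  centers <- X[sample(n, k), , drop = FALSE]

  sqdist <- function(X, C) {
    # n x k matrix of squared Euclidean distances
    outer(rowSums(X^2), rep(1, nrow(C))) +
      outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  }
  memberships_from <- function(d2) {
    d2 <- pmax(d2, 0)
    expo <- d2^(-1 / (m - 1))
    zero <- d2 < 1e-300           # coincident with a center
    u <- expo / rowSums(expo)
    hit <- which(rowSums(zero) > 0)
    for (i in hit) {
      u[i, ] <- 0
      u[i, which(zero[i, ])[1]] <- 1
    }
    u
  }

  obj_trace <- numeric()
  converged <- FALSE
  iter <- 0L
  u <- memberships_from(sqdist(X, centers))
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers_new <- (t(um) %*% X) / colSums(um)
    d2 <- sqdist(X, centers_new)
    u <- memberships_from(d2)
    obj_trace <- c(obj_trace, sum(u^m * pmax(d2, 0)))
    shift <- max(abs(centers_new - centers))
    centers <- centers_new
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  best <- max.col(u, ties.method = "first")
  best_val <- u[cbind(seq_len(n), best)]
  assignment <- ifelse(best_val >= min_membership, best, NA_integer_)
  names(assignment) <- rownames(X)
  rownames(u) <- rownames(X)
  colnames(u) <- paste0("cluster", seq_len(k))
  structure(list(k = k, m = m, memberships = u, centers = centers,
                 assignment = assignment, converged = converged,
                 iterations = iter, objective_trace = obj_trace,
                 min_membership = min_membership, seed = seed),
            class = "fx_fcm")
}

#' Heuristic fuzzifier estimate
#'
#' The empirical formula relating the fuzzifier to the data dimensions
#' (N genes, D time points):
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param profiles Genes x time-points matrix (or a list with dims).
#' @return The fuzzifier m (> 1).
#' @export
estimate_fuzzifier <- function(profiles) {
  N <- nrow(profiles)
  D <- ncol(profiles)
  assert(!is.null(N) && N >= 2 && D >= 2, "need at least 2 genes and 2 time points")
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}
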