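# Partial least squares against the specific oxygen uptake rate, and the
# variable-importance-in-projection (VIP) screen: metabolites whose VIP
# exceeds 1 are the ones whose pool-size changes track the oxygen supply.
#
# The fit is classical single-response NIPALS (PLS1): per component a,
#   w_a = X'y / ||X'y||,  t_a = X w_a,  p_a = X't_a / t_a't_a,
#   q_a = y't_a / t_a't_a,
# followed by deflation of X and y. SS_a = q_a^2 * t_a't_a is the response
# sum of squares explained by component a, and
#   VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )
# (weights are unit-norm), so mean_j VIP_j^2 = 1 identically.

#' Fit a single-response PLS model (NIPALS)
#'
#' @param X Samples x variables matrix, columns centered (autoscaled by
#'   the usual preprocessing).
#' @param y Response per sample (e.g. q_O2); centered internally.
#' @param n_components Number of latent components A; truncated when the
#'   residual X carries no further covariance with y.
#' @return A list of class `fx_pls`: `weights` (p x A), `scores` (n x A),
#'   `x_loadings`, `y_loadings` (length A), `ss_response` (SS_a per
#'   component), `fitted`, `residual_y`.
#' @export
fit_pls <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  assert(nrow(X) == length(y), "X and y disagree on the number of samples")
  assert(var(y) > 0, "response y has zero variance")
  assert(n_components >= 1, "need at least one component")
  y0 <- y - mean(y)
  Xd <- sweep(X, 2, colMeans(X))
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(X), 0)
  qv <- ss <- numeric(0)
  yd <- y0
  for (a in seq_len(n_components)) {
    wv <- crossprod(Xd, yd)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12 * max(1, sqrt(sum(y0^2)))) {
      message("PLS stopped at ", a - 1L, " components (no residual covariance)")
      break
    }
    wv <- drop(wv / nw)
    tv <- drop(Xd %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(Xd, tv)) / tt
    qa <- sum(yd * tv) / tt
    W <- cbind(W, wv); Tm <- cbind(Tm, tv); P <- cbind(P, pv)
    qv <- c(qv, qa)
    ss <- c(ss, qa^2 * tt)
    Xd <- Xd - tv %*% t(pv)
    yd <- yd - qa * tv
  }
  assert(ncol(W) >= 1, "PLS found no informative component")
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(ncol(W))))
  structure(list(weights = W, scores = Tm, x_loadings = P, y_loadings = qv,
                 ss_response = ss, n_components = ncol(W),
                 fitted = mean(y) + (y0 - yd), residual_y = yd,
                 x_center = colMeans(X), y_center = mean(y)),
            class = "fx_pls")
}

#' VIP scores of a fitted PLS model
#'
#' `VIP_j = sqrt(p * sum_a SS_a (w_ja/||w_a||)^2 / sum_a SS_a)`; the mean
#' of squared VIPs equals 1 by construction, so VIP > 1 marks variables
#' contributing more than average to the explained response — the
#' screening rule used for metabolite selection.
#'
#' @param model An `fx_pls`.
#' @return A list of class `fx_vip`: `vip` (named scores) and `selected`
#'   (logical, VIP > 1).
#' @export
compute_vip <- function(model) {
  ss <- model$ss_response
  assert(any(ss > 0), "no explained response (all SS_a = 0)")
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip <- sqrt(p * as.vector(wn2 %*% ss) / sum(ss))
  names(vip) <- rownames(W)
  structure(list(vip = vip, selected = vip > 1, n_components = ncol(W)),
            class = "fx_vip")
}

#' Choose the number of PLS components by leave-one-out Q2
#'
#' Q2(A) = 1 - PRESS(A)/SS_tot from leave-one-out cross-validation; the A
#' maximizing Q2 is returned (ties to the smaller A).
#'
#' @param X,y As in [fit_pls()].
#' @param max_components Largest A to try.
#' @return List with `n_components` and the `q2` profile.
#' @export
choose_ncomp_q2 <- function(X, y, max_components = min(5, ncol(X), nrow(X) - 2)) {
  X <- as.matrix(X)
  n <- nrow(X)
  press <- numeric(max_components)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components = max_components)
    # predict the held-out sample at each component count
    xc <- X[i, ] - fit$x_center
    pred <- fit$y_center
    for (a in seq_len(fit$n_components)) {
      t_new <- sum(xc * fit$weights[, a])
      pred <- pred + fit$y_loadings[a] * t_new
      xc <- xc - t_new * fit$x_loadings[, a]
      press[a] <- press[a] + (y[i] - pred)^2
    }
    if (fit$n_components < max_components)
      press[seq(fit$n_components + 1L, max_components)] <-
        press[seq(fit$n_components + 1L, max_components)] + (y[i] - pred)^2
  }
  q2 <- 1 - press / sum((y - mean(y))^2)
  list(n_components = which.max(q2), q2 = q2)
}

#' PLS-DA: discriminant PLS with dummy-coded class labels
#'
#' Multi-response NIPALS with the class-indicator matrix as Y; provided
#' as the categorical alternative to regressing on a continuous rate.
#'
#' @param X Samples x variables matrix.
#' @param classes Factor of sample classes (e.g. fermentation phase).
#' @param n_components Number of components.
#' @return An `fx_pls`-like list with per-component response SS summed
#'   over the dummy columns, suitable for [compute_vip()].
#' @export
fit_plsda <- function(X, classes, n_components = 2) {
  classes <- as.factor(classes)
  assert(nlevels(classes) >= 2, "need at least two classes")
  Y <- sapply(levels(classes), function(l) as.numeric(classes == l))
  X <- as.matrix(X)
  Xd <- sweep(X, 2, colMeans(X))
  Yd <- sweep(Y, 2, colMeans(Y))
  p <- ncol(X)
  W <- matrix(0, p, 0); Tm <- matrix(0, nrow(X), 0)
  ss <- numeric(0)
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    wv <- NULL
    for (it in 1:500) {
      wv_new <- crossprod(Xd, u); wv_new <- wv_new / sqrt(sum(wv_new^2))
      tv <- Xd %*% wv_new
      cv <- crossprod(Yd, tv) / sum(tv^2)
      u_new <- Yd %*% cv / sum(cv^2)
      if (!is.null(wv) && max(abs(wv_new - wv)) < 1e-10) { wv <- wv_new; break }
      wv <- wv_new; u <- u_new
    }
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(Xd, tv) / tt
    cv <- crossprod(Yd, tv) / tt
    W <- cbind(W, wv); Tm <- cbind(Tm, tv)
    ss <- c(ss, sum((tv %*% t(cv))^2))
    Xd <- Xd - tv %*% t(pv)
    Yd <- Yd - tv %*% t(cv)
  }
  rownames(W) <- colnames(X)
  structure(list(weights = W, scores = Tm, ss_response = ss,
                 n_components = ncol(W)),
            class = c("fx_plsda", "fx_pls"))
}
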