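# Linear-programming backend.
#
# The solver contract required by the flux code is minimal: return an
# optimal basic solution of  max/min c'v  s.t.  A v = rhs, lb <= v <= ub,
# with the objective reproducible to ~1e-9. All flux bounds in this
# package are finite (the conventional +/-1000 open bound), so every LP
# is bounded and "unbounded" cannot occur. The engine is a dense
# two-phase bounded-variable primal simplex with Bland's anti-cycling
# rule — deliberately simple and deterministic; the flux polytopes here
# have at most a few dozen variables, where exactness matters more than
# speed. Tests only assert solver-independent quantities (objective
# value, total absolute flux, uniquely determined fluxes) and check the
# engine against exhaustive vertex enumeration.

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Equality-constraint matrix (m x n, may have 0 rows):
#'   `A v = rhs`.
#' @param rhs Right-hand side (defaults to zeros).
#' @param lb,ub Finite variable bounds.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot / feasibility tolerance.
#' @return List with `status` (`"optimal"` / `"infeasible"`), `value`
#'   (objective at the optimum) and `x` (an optimal basic solution),
#'   the latter two `NA`/`NULL` unless optimal.
#' @export
solve_lp <- function(obj, A, rhs = NULL, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  A <- as.matrix(A)
  if (is.null(rhs)) rhs <- rep(0, nrow(A))
  assert(ncol(A) == n || nrow(A) == 0L, "A has ", ncol(A), " columns, expected ", n)
  assert(length(lb) == n && length(ub) == n, "bound length mismatch")
  assert(all(is.finite(lb)) && all(is.finite(ub)),
         "solve_lp requires finite bounds; replace infinite bounds with the ",
         "conventional +/-1000 open bound")
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_, x = NULL))

  cvec <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)
  res <- lp_simplex(cvec, A, as.numeric(rhs), as.numeric(lb), as.numeric(ub), tol)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, x = NULL))
  list(status = "optimal", value = sum(obj * res$x), x = res$x)
}

# two-phase bounded-variable primal simplex (minimization), Bland's rule
lp_simplex <- function(cvec, A, b, lb, ub, tol = 1e-9) {
  n <- length(cvec)
  m <- nrow(A)
  if (m == 0L) {  # separable: each variable at its best bound
    x <- ifelse(cvec > 0, lb, ub)
    x[cvec == 0] <- lb[cvec == 0]
    return(list(status = "optimal", x = x))
  }

  # normalize rows so artificial variables start non-negative
  x0 <- lb
  r <- b - as.vector(A %*% x0)
  flip <- r < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  r <- abs(r)

  art_ub <- sum(r) + 1
  Ax <- cbind(A, diag(m))                       # n originals + m artificials
  lbx <- c(lb, rep(0, m))
  ubx <- c(ub, rep(art_ub, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)                 # status of nonbasic vars
  xval <- c(x0, r)

  run_phase <- function(cost, basis, at_upper, xval, max_iter) {
    for (it in seq_len(max_iter)) {
      B <- Ax[, basis, drop = FALSE]
      Binv_applied <- function(v) solve(B, v)
      y <- drop(solve(t(B), cost[basis]))
      nonbasic <- setdiff(seq_len(n + m), basis)
      d <- cost[nonbasic] - drop(y %*% Ax[, nonbasic, drop = FALSE])
      enter_ok <- (!at_upper[nonbasic] & d < -tol) |
                  (at_upper[nonbasic] & d > tol)
      if (!any(enter_ok))
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xval = xval))
      j <- nonbasic[enter_ok][which.min(nonbasic[enter_ok])]   # Bland
      dj <- cost[j] - sum(y * Ax[, j])
      dir <- if (at_upper[j]) -1 else 1                        # movement of x_j
      w <- drop(Binv_applied(Ax[, j])) * dir
      # ratio test: basic vars move by -w * t as x_j moves by dir * t
      xB <- xval[basis]
      t_max <- ubx[j] - lbx[j]                                 # bound flip
      leave <- 0L
      for (k in seq_len(m)) {
        if (w[k] > tol) {
          lim <- (xB[k] - lbx[basis[k]]) / w[k]
        } else if (w[k] < -tol) {
          lim <- (xB[k] - ubx[basis[k]]) / w[k]
        } else next
        if (lim < t_max - 1e-12 ||
            (lim < t_max + 1e-12 && leave != 0L && basis[k] < basis[leave])) {
          t_max <- lim
          leave <- k
        }
      }
      t_max <- max(t_max, 0)
      xval[basis] <- xB - w * t_max
      xval[j] <- xval[j] + dir * t_max
      if (leave == 0L) {                                       # bound flip
        at_upper[j] <- !at_upper[j]
      } else {
        out <- basis[leave]
        at_upper[out] <- w[leave] < 0                          # hit its upper bound
        xval[out] <- if (at_upper[out]) ubx[out] else lbx[out]
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
    list(status = "iteration_limit", basis = basis, at_upper = at_upper,
         xval = xval)
  }

  max_iter <- 1000L + 200L * (n + m)

  # phase 1: minimize the artificial sum
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, basis, at_upper, xval, max_iter)
  assert(ph1$status == "optimal", "simplex phase 1 hit the iteration limit")
  if (sum(ph1$xval[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL))

  # phase 2: pin artificials to zero and optimize the true objective
  ubx <- c(ub, rep(0, m))
  xval <- ph1$xval
  xval[n + seq_len(m)] <- 0
  cost2 <- c(cvec, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_upper, xval, max_iter)
  assert(ph2$status == "optimal", "simplex phase 2 hit the iteration limit")
  x <- ph2$xval[seq_len(n)]
  list(status = "optimal", x = pmin(pmax(x, lb), ub))
}

#' Enumerate the vertices of a flux polytope
#'
#' Exhaustively lists the basic feasible solutions of
#' `{v : A v = rhs, lb <= v <= ub}` by trying every basis (subset of
#' `rank(A)` columns) against every lower/upper assignment of the
#' non-basic variables. Exponential — intended as an independent oracle
#' for networks of about a dozen reactions (or larger networks whose
#' `n - rank(A)` is small), not as a solver.
#'
#' @param A Equality-constraint matrix.
#' @param rhs Right-hand side (defaults to zeros).
#' @param lb,ub Finite bounds.
#' @param tol Feasibility tolerance.
#' @return Matrix with one vertex per row (possibly 0 rows).
#' @export
enumerate_lp_vertices <- function(A, rhs = NULL, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- length(lb)
  if (is.null(rhs)) rhs <- rep(0, nrow(A))
  qrA <- qr(t(A))            # row space of A
  r <- qrA$rank
  rows <- qrA$pivot[seq_len(r)]
  Ar <- A[rows, , drop = FALSE]; br <- rhs[rows]
  verts <- list()
  basis_sets <- if (r > 0) utils::combn(n, r, simplify = FALSE) else list(integer())
  for (basic in basis_sets) {
    B <- Ar[, basic, drop = FALSE]
    if (r > 0 && abs(det(B)) < 1e-10) next
    nonbasic <- setdiff(seq_len(n), basic)
    k <- length(nonbasic)
    for (mask in seq_len(2^k) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      v <- numeric(n)
      v[nonbasic] <- ifelse(at_ub, ub[nonbasic], lb[nonbasic])
      if (r > 0) {
        rhs_b <- br - if (k) Ar[, nonbasic, drop = FALSE] %*% v[nonbasic] else 0
        v[basic] <- solve(B, rhs_b)
      }
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        v <- pmin(pmax(v, lb), ub)
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 9)), , drop = FALSE]
}
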