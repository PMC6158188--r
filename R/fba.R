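# Flux balance analysis (FBA) and parsimonious FBA (pFBA).
#
# FBA:   max/min Z = C'v   s.t.  S v = 0,  lb <= v <= ub.
# pFBA:  a second LP that fixes Z at the FBA optimum, splits every
#        reversible reaction into non-negative forward/backward halves and
#        minimizes the total flux sum — i.e. the enzymatically economical
#        flux distribution among all optimal ones.

new_fba_solution <- function(status, objective_value = NA_real_, fluxes = NULL,
                             total_absolute_flux = NA_real_) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, total_absolute_flux = total_absolute_flux),
            class = "fx_fba_solution")
}

#' @export
print.fx_fba_solution <- function(x, ...) {
  cat(sprintf("<fx_fba_solution> status=%s Z=%s", x$status,
              format(x$objective_value)))
  if (is.finite(x$total_absolute_flux))
    cat(sprintf("  sum|v|=%.6g", x$total_absolute_flux))
  cat("\n")
  invisible(x)
}

fba_matrices <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model)$values)
  b <- reaction_bounds(model)
  obj <- numeric(n_reactions(model))
  names(obj) <- names(model$reactions)
  obj[names(model$objective)] <- model$objective
  list(S = S, lb = b$lb, ub = b$ub, obj = obj)
}

#' Flux balance analysis
#'
#' @param model A validated `fx_model` with a non-empty objective.
#' @param sense Optimization direction for `Z = C'v`.
#' @return An `fx_fba_solution`: `status` (`"optimal"`/`"infeasible"`),
#'   `objective_value` and a named flux vector (one of possibly many
#'   optimal vertices; only the objective is solver-independent).
#' @export
solve_fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  assert(length(model$objective) > 0, "model has an empty objective")
  mm <- fba_matrices(model)
  res <- solve_lp(unname(mm$obj), mm$S, lb = unname(mm$lb), ub = unname(mm$ub),
                  sense = sense)
  if (res$status != "optimal") return(new_fba_solution(res$status))
  new_fba_solution("optimal", res$value,
                   fluxes = setNames(res$x, names(model$reactions)))
}

#' Parsimonious flux balance analysis
#'
#' @param model A validated `fx_model`.
#' @param sense Direction of the primary objective (growth maximization by
#'   convention).
#' @param tol_obj Relative tolerance with which the primary optimum is held
#'   fixed during flux minimization.
#' @return An `fx_fba_solution` with `total_absolute_flux` filled in
#'   (`sum(|v|)` of the returned vector).
#' @export
solve_pfba <- function(model, sense = c("max", "min"), tol_obj = 1e-9) {
  sense <- match.arg(sense)
  stage1 <- solve_fba(model, sense)
  if (stage1$status != "optimal") return(stage1)
  z <- stage1$objective_value
  mm <- fba_matrices(model)
  n <- length(mm$lb)

  split <- which(mm$lb < 0)          # reversible: v = f - b, f,b >= 0
  keep <- setdiff(seq_len(n), split)
  # columns: kept originals, then (f, b) pairs for split reactions
  S2 <- cbind(mm$S[, keep, drop = FALSE],
              mm$S[, split, drop = FALSE], -mm$S[, split, drop = FALSE])
  lb2 <- c(mm$lb[keep], pmax(0, mm$lb[split]), pmax(0, -mm$ub[split]))
  ub2 <- c(mm$ub[keep], pmax(0, mm$ub[split]), pmax(0, -mm$lb[split]))
  obj2 <- c(mm$obj[keep], mm$obj[split], -mm$obj[split])

  # hold the primary objective at its optimum (within relative tol_obj) by
  # an equality row; the stage-1 vertex itself satisfies it, so it is
  # always feasible
  A <- rbind(S2, obj2)
  rhs <- c(rep(0, nrow(S2)), z)
  res <- solve_lp(rep(1, ncol(S2)), A, rhs = rhs, lb = unname(lb2),
                  ub = unname(ub2), sense = "min")
  assert(res$status == "optimal",
         "pFBA stage 2 unexpectedly ", res$status,
         " (stage 1 was optimal); this indicates a solver failure")
  v <- numeric(n)
  v[keep] <- res$x[seq_along(keep)]
  nf <- length(keep)
  ns <- length(split)
  v[split] <- res$x[nf + seq_len(ns)] - res$x[nf + ns + seq_len(ns)]
  z2 <- sum(mm$obj * v)
  assert(abs(z2 - z) <= tol_obj * max(1, abs(z)),
         "pFBA drifted from the FBA optimum: ", z2, " vs ", z)
  new_fba_solution("optimal", z2,
                   fluxes = setNames(v, names(model$reactions)),
                   total_absolute_flux = res$value)
}

#' Flux variability over the optimal face (diagnostic)
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' primary objective is held at (a fraction of) its optimum. Reported
#' because a single pFBA vector hides degeneracy: a wide range flags fluxes
#' that are not uniquely determined by the constraints.
#'
#' @param model A validated `fx_model`.
#' @param fraction Fraction of the optimum to enforce (`C'v >= fraction*Z`
#'   via a bounded slack).
#' @return Data frame: reaction, min_flux, max_flux, width.
#' @export
flux_variability <- function(model, fraction = 1 - 1e-6) {
  stage1 <- solve_fba(model)
  assert(stage1$status == "optimal", "FVA requires an optimal FBA solution")
  z <- stage1$objective_value
  mm <- fba_matrices(model)
  n <- length(mm$lb)
  # slack s >= 0 turns C'v - s = fraction*z into C'v >= fraction*z
  A <- rbind(cbind(mm$S, 0), c(unname(mm$obj), -1))
  rhs <- c(rep(0, nrow(mm$S)), fraction * z)
  slack_ub <- abs(z) * (1 - fraction) + max(1, abs(z)) * 1e-7
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    e <- c(numeric(n), 0); e[i] <- 1
    lo[i] <- solve_lp(e, A, rhs = rhs, lb = c(unname(mm$lb), 0),
                      ub = c(unname(mm$ub), slack_ub), sense = "min")$value
    hi[i] <- solve_lp(e, A, rhs = rhs, lb = c(unname(mm$lb), 0),
                      ub = c(unname(mm$ub), slack_ub), sense = "max")$value
  }
  data.frame(reaction = names(model$reactions), min_flux = lo, max_flux = hi,
             width = hi - lo, row.names = NULL)
}
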