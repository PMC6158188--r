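# Independent oracles used across the suite. Everything here is kept
# deliberately naive (dense construction, exhaustive enumeration, direct
# formula evaluation) so it shares no code path with the implementation
# it checks.

# dense stoichiometric matrix straight from the reaction list
dense_stoich_oracle <- function(model) {
  met_ids <- names(model$metabolites)
  S <- matrix(0, length(met_ids), length(model$reactions),
              dimnames = list(met_ids, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    for (mid in names(st)) S[mid, j] <- S[mid, j] + st[[mid]]
  }
  S
}

# vertices of a model's flux polytope, after folding variables fixed by
# equal bounds into the right-hand side (keeps enumeration tractable)
model_vertices <- function(model, extra_A = NULL, extra_rhs = NULL) {
  S <- dense_stoich_oracle(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  A <- rbind(S, extra_A)
  rhs <- c(rep(0, nrow(S)), extra_rhs)
  fixed <- which(lb == ub)
  free <- setdiff(seq_along(lb), fixed)
  rhs2 <- rhs - if (length(fixed)) A[, fixed, drop = FALSE] %*% lb[fixed] else 0
  V <- enumerate_lp_vertices(A[, free, drop = FALSE], rhs = as.vector(rhs2),
                             lb = lb[free], ub = ub[free])
  if (nrow(V) == 0) return(matrix(numeric(), 0, length(lb)))
  full <- matrix(rep(lb, each = nrow(V)), nrow(V))
  full[, free] <- V
  colnames(full) <- names(model$reactions)
  full
}

# FBA optimum by exhaustive enumeration
fba_oracle <- function(model, sense = "max") {
  V <- model_vertices(model)
  if (nrow(V) == 0) return(list(feasible = FALSE))
  obj <- numeric(ncol(V))
  names(obj) <- colnames(V)
  obj[names(model$objective)] <- model$objective
  z <- as.vector(V %*% obj)
  best <- if (sense == "max") max(z) else min(z)
  list(feasible = TRUE, value = best,
       vertices = V[abs(z - best) < 1e-7, , drop = FALSE])
}

# minimum total absolute flux over the optimal face, by enumerating the
# vertices of the split (forward/backward) polytope with the objective
# pinned; the L1 minimum over a polytope is attained at a vertex of the
# split formulation
pfba_oracle <- function(model) {
  z <- fba_oracle(model)$value
  S <- dense_stoich_oracle(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- numeric(length(lb)); names(obj) <- names(model$reactions)
  obj[names(model$objective)] <- model$objective
  split <- which(lb < 0)
  keep <- setdiff(seq_along(lb), split)
  S2 <- cbind(S[, keep, drop = FALSE], S[, split, drop = FALSE],
              -S[, split, drop = FALSE])
  lb2 <- c(lb[keep], pmax(0, lb[split]), pmax(0, -ub[split]))
  ub2 <- c(ub[keep], pmax(0, ub[split]), pmax(0, -lb[split]))
  obj2 <- c(obj[keep], obj[split], -obj[split])
  A <- rbind(S2, obj2)
  rhs <- c(rep(0, nrow(S2)), z)
  V <- enumerate_lp_vertices(A, rhs = rhs, lb = lb2, ub = ub2)
  stopifnot(nrow(V) > 0)
  min(rowSums(V))
}

# quadratic-time complete-linkage agglomeration: returns merge heights and
# the partition after each merge
agglomerate_oracle <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric()
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(sort(merged)))
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(groups) {
  sets <- lapply(groups, function(g) paste(sort(g), collapse = ","))
  paste(sort(unlist(sets)), collapse = "|")
}

expect_feasible_solution <- function(model, sol, tol_bal = 1e-6, tol_bd = 1e-9) {
  S <- dense_stoich_oracle(model)
  v <- sol$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), tol_bal)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  expect_true(all(v >= lb - tol_bd) && all(v <= ub + tol_bd))
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
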