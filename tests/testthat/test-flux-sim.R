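# FBA / pFBA solvers, phase constraints, relative fluxes and prediction
# validation, all checked against enumeration oracles.

test_that("FBA on the chain equals the uptake bound and respects closure", {
  m <- make_toy_model("chain")
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(abs(sol$fluxes)), rep(10, 3))
  expect_feasible_solution(m, sol)
  # closed system: no uptake, no flux
  m0 <- set_bounds(m, "EX_a", lb = 0, ub = 0)
  sol0 <- solve_fba(m0)
  expect_equal(sol0$objective_value, 0)
  expect_equal(max(abs(sol0$fluxes)), 0)
})

test_that("FBA objective matches exhaustive vertex enumeration on random nets", {
  for (s in 1:8) {
    m <- make_random_network(seed = s)
    sol <- solve_fba(m)
    orc <- fba_oracle(m)
    expect_true(orc$feasible)
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective_value, orc$value, tolerance = 1e-8)
    expect_feasible_solution(m, sol)
    # minimization direction too
    expect_equal(solve_fba(m, "min")$objective_value,
                 fba_oracle(m, "min")$value, tolerance = 1e-8)
  }
})

test_that("pFBA picks the short diamond path and minimizes total flux", {
  m <- make_toy_model("diamond")
  fba <- solve_fba(m)
  sol <- solve_pfba(m)
  expect_equal(sol$objective_value, fba$objective_value, tolerance = 1e-8)
  expect_equal(sol$total_absolute_flux, 40)           # EX_a + 2-step path + EX_b
  expect_equal(sol$total_absolute_flux, pfba_oracle(m), tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[c("P2_1", "P2_2", "P2_3")]), rep(0, 3))
  # dominance: never more total flux than any plain-FBA optimum
  expect_lte(sol$total_absolute_flux, sum(abs(fba$fluxes)) + 1e-9)
})

test_that("pFBA equals FBA on a network with a unique optimum", {
  m <- make_toy_model("chain")
  expect_equal(solve_pfba(m)$fluxes, solve_fba(m)$fluxes, tolerance = 1e-9)
})

test_that("pFBA preserves the objective and dominates on random networks", {
  for (s in 1:6) {
    m <- make_random_network(seed = s)
    fba <- solve_fba(m)
    sol <- solve_pfba(m)
    expect_equal(sol$objective_value, fba$objective_value,
                 tolerance = 1e-8 * max(1, abs(fba$objective_value)))
    expect_lte(sol$total_absolute_flux, sum(abs(fba$fluxes)) + 1e-8)
    expect_feasible_solution(m, sol)
  }
})

test_that("loosening a bound never decreases the maximized objective", {
  m <- make_toy_model("core")
  m <- set_bounds(m, "EX_glc", lb = -2)
  z1 <- solve_fba(m)$objective_value
  z2 <- solve_fba(set_bounds(m, "EX_glc", lb = -4))$objective_value
  expect_gte(z2, z1 - 1e-9)
  z3 <- solve_fba(set_bounds(m, "EX_o2", lb = -0.5))$objective_value
  expect_lte(z3, z1 + 1e-9)   # tightening cannot help
})

test_that("scaling all bounds scales optimal fluxes proportionally", {
  m <- make_toy_model("core")
  m <- set_bounds(m, "EX_glc", lb = -2)
  s1 <- solve_pfba(m)
  k <- 3.5
  m2 <- m
  for (rid in names(m2$reactions)) {
    r <- m2$reactions[[rid]]
    m2 <- set_bounds(m2, rid, lb = r$lower_bound * k, ub = r$upper_bound * k)
  }
  s2 <- solve_pfba(m2)
  expect_equal(s2$objective_value, k * s1$objective_value, tolerance = 1e-7)
  expect_equal(s2$fluxes, s1$fluxes * k, tolerance = 1e-6)
})

test_that("phase constraints set exactly five bound groups, uptake-negative", {
  m <- make_toy_model("core")
  pc <- phase_constraints(24, q_S = 1.2, q_O2 = 2.5, q_P = 0.05,
                          q_byproducts = c(EX_pol = 0.3), m_ATP = 0.8,
                          tolerance = 0.1)
  m2 <- apply_phase_constraints(m, pc)
  expect_equal(m2$reactions$EX_glc$lower_bound, -1.2 * 1.1)
  expect_equal(m2$reactions$EX_glc$upper_bound, -1.2 * 0.9)
  expect_equal(m2$reactions$EX_o2$lower_bound, -2.5 * 1.1)
  expect_equal(m2$reactions$EX_prot$lower_bound, 0.05 * 0.9)
  expect_equal(m2$reactions$EX_pol$upper_bound, 0.3 * 1.1)
  expect_equal(m2$reactions$ATPM$lower_bound, 0.8 * 0.9)
  expect_equal(m2$reactions$ATPM$upper_bound, 0.8 * 1.1)
  # everything else untouched
  touched <- c("EX_glc", "EX_o2", "EX_prot", "EX_pol", "ATPM")
  for (rid in setdiff(names(m$reactions), touched)) {
    expect_equal(m2$reactions[[rid]]$lower_bound, m$reactions[[rid]]$lower_bound)
    expect_equal(m2$reactions[[rid]]$upper_bound, m$reactions[[rid]]$upper_bound)
  }
  # zero tolerance degenerates to equality constraints
  m3 <- apply_phase_constraints(m, phase_constraints(24, 1.2, 2.5, 0.05,
                                                     m_ATP = 0.8, tolerance = 0))
  expect_equal(m3$reactions$EX_glc$lower_bound, m3$reactions$EX_glc$upper_bound)
  # missing mapped reaction is a configuration error naming the rate
  expect_error(apply_phase_constraints(m, pc, map = list(q_S = "nope")),
               "q_S", class = "fluxomix_config_error")
})

test_that("an obligate-aerobic demand makes anoxic phases infeasible", {
  m <- make_toy_model("core")
  # without oxygen, substrate-level ATP cannot cover this maintenance
  pc <- phase_constraints(30, q_S = 1, q_O2 = 0, q_P = 0, m_ATP = 2,
                          tolerance = 0)
  sol <- solve_pfba(apply_phase_constraints(m, pc))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
  expect_null(sol$fluxes)
})

test_that("relative fluxes are per 100 mol of reference", {
  sol <- structure(list(status = "optimal",
                        fluxes = c(EX_glc = -10, A = 4, B = 6)),
                   class = "fx_fba_solution")
  rel <- compute_relative_flux(sol, "EX_glc")
  expect_equal(unname(rel), c(-100, 40, 60))
  sol$fluxes["EX_glc"] <- 1e-12
  expect_error(compute_relative_flux(sol, "EX_glc"), "absolute fluxes")
  m <- make_toy_model("chain")
  s <- solve_fba(m)
  expect_equal(unname(abs(compute_relative_flux(s, "EX_a"))), rep(100, 3))
})

test_that("simulate_phases handles empty input and reports infeasible phases", {
  m <- make_toy_model("core")
  expect_equal(simulate_phases(m, list()), list())
  phases <- list(phase_constraints(10, 1, 2, 0.02, m_ATP = 0.5, tolerance = 0.05),
                 phase_constraints(20, 1, 0, 0, m_ATP = 2, tolerance = 0))
  res <- simulate_phases(m, phases)
  expect_equal(res[[1]]$solution$status, "optimal")
  expect_equal(res[[2]]$solution$status, "infeasible")
  expect_equal(res[[1]]$mu_predicted,
               res[[1]]$solution$fluxes[["BIOMASS"]])
  expect_equal(res[[1]]$qCO2_predicted,
               res[[1]]$solution$fluxes[["EX_co2"]])
})

test_that("validate_predictions computes exact and perturbed errors", {
  m <- make_toy_model("core")
  sim <- simulate_fermentation(m, fermentation_scenario(noise_sd = 0,
                                                        time_grid = c(18, 36)))
  res <- simulate_phases(m, sim$phases)
  val <- validate_predictions(res, sim$measured)
  expect_equal(val$mean_rel_error_mu, 0, tolerance = 1e-9)
  expect_equal(val$mean_rel_error_qCO2, 0, tolerance = 1e-9)
  # +10% perturbation of the measurements reads back as 10% relative error
  meas <- sim$measured
  meas$mu <- meas$mu * 1.1
  val2 <- validate_predictions(res, meas)
  expect_equal(val2$per_phase$mu_rel_error, rep(0.1 / 1.1, 2), tolerance = 1e-9)
  expect_error(validate_predictions(res, data.frame(time_h = c(1, 2),
                                                    mu = 1:2, qCO2 = 1:2)),
               "unmatched")
})

test_that("flux variability flags the diamond's degenerate routes", {
  m <- make_toy_model("diamond")
  fva <- flux_variability(m)
  wide <- fva$reaction[fva$width > 1]
  expect_true(all(c("P1_1", "P2_1") %in% wide))
  expect_lt(fva$width[fva$reaction == "EX_a"], 1e-4)   # uptake pinned at optimum
})
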