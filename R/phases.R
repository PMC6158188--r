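# Per-phase application of measured specific rates as flux constraints,
# snapshot simulation of a fed-batch time course, and validation of the
# predicted growth rate and CO2 evolution against measurements.
#
# Sign convention: exchange flux negative = uptake, positive = secretion.
# Measured rates are entered as positive magnitudes and negated internally
# where they are uptakes (glucose, oxygen).

#' Measured specific rates for one fermentation phase
#'
#' @param time_h Fermentation time (h).
#' @param q_S Glucose uptake rate (mmol/gDCW/h, positive magnitude).
#' @param q_O2 Oxygen uptake rate (mmol/gDCW/h, positive magnitude).
#' @param q_P Product (glucoamylase) secretion rate (mmol residue/gDCW/h).
#' @param q_byproducts Named numeric: by-product exchange reaction id ->
#'   secretion rate.
#' @param m_ATP Non-growth ATP maintenance (mmol ATP/gDCW/h).
#' @param tolerance Relative half-width of the allowed band around each
#'   measured value (measurement error allowance); in `[0, 1)`.
#' @return A list of class `fx_phase`.
#' @export
phase_constraints <- function(time_h, q_S, q_O2, q_P = 0,
                              q_byproducts = numeric(), m_ATP = 0,
                              tolerance = 0.05) {
  assert(time_h >= 0, "time_h must be >= 0")
  assert(all(c(q_S, q_O2, q_P, m_ATP, q_byproducts) >= 0),
         "rates are positive magnitudes; got a negative value at t=", time_h)
  assert(tolerance >= 0 && tolerance < 1, "tolerance must be in [0, 1)")
  structure(list(time_h = time_h, q_S = q_S, q_O2 = q_O2, q_P = q_P,
                 q_byproducts = q_byproducts, m_ATP = m_ATP,
                 tolerance = tolerance),
            class = "fx_phase")
}

#' Default mapping from measured rates to model reactions
#'
#' Looks up the conventional exchange ids (`EX_glc`, `EX_o2`, `EX_co2`,
#' `EX_prot`) and the model's declared ATP maintenance reaction. Override
#' any entry for models with other naming.
#'
#' @param model An `fx_model`.
#' @return Named list: q_S, q_O2, q_CO2, q_P, m_ATP -> reaction id.
#' @export
default_exchange_map <- function(model) {
  list(q_S = "EX_glc", q_O2 = "EX_o2", q_CO2 = "EX_co2", q_P = "EX_prot",
       m_ATP = model$atp_maintenance_reaction_id)
}

band <- function(q, tol) sort(c(q * (1 - tol), q * (1 + tol)))

#' Constrain a model with one phase's measured rates
#'
#' Glucose and oxygen exchange bounds are set to
#' `[-q(1+tol), -q(1-tol)]` (uptake-negative); product and by-product
#' exchanges to `[q(1-tol), q(1+tol)]`; the ATP maintenance flux is fixed
#' to `[m_ATP(1-tol), m_ATP(1+tol)]`. All other bounds are untouched.
#'
#' @param model An `fx_model`.
#' @param pc A [phase_constraints()] object.
#' @param map Rate -> reaction-id mapping, see [default_exchange_map()].
#' @return A constrained copy of the model.
#' @export
apply_phase_constraints <- function(model, pc, map = default_exchange_map(model)) {
  need <- function(rate) {
    rid <- map[[rate]]
    assert(!is.null(rid) && !is.na(rid) && rid %in% names(model$reactions),
           "no model reaction mapped for measured rate ", rate,
           " (looked for '", rid %||% "<missing>", "')",
           class = "fluxomix_config_error")
    rid
  }
  tol <- pc$tolerance
  up <- band(pc$q_S, tol)
  model <- set_bounds(model, need("q_S"), lb = -up[2], ub = -up[1])
  up <- band(pc$q_O2, tol)
  model <- set_bounds(model, need("q_O2"), lb = -up[2], ub = -up[1])
  sec <- band(pc$q_P, tol)
  model <- set_bounds(model, need("q_P"), lb = sec[1], ub = sec[2])
  for (rid in names(pc$q_byproducts)) {
    assert(rid %in% names(model$reactions),
           "by-product exchange not in model: ", rid,
           class = "fluxomix_config_error")
    sec <- band(pc$q_byproducts[[rid]], tol)
    model <- set_bounds(model, rid, lb = sec[1], ub = sec[2])
  }
  atp <- band(pc$m_ATP, tol)
  model <- set_bounds(model, need("m_ATP"), lb = atp[1], ub = atp[2])
  model
}

#' Relative fluxes (mol per 100 mol of a reference flux)
#'
#' @param sol An optimal `fx_fba_solution`.
#' @param reference_reaction Reaction id of the reference (normally the
#'   glucose exchange); the reference itself maps to +/-100.
#' @return Named numeric vector of `flux / |reference| * 100`.
#' @export
compute_relative_flux <- function(sol, reference_reaction) {
  assert(sol$status == "optimal", "no fluxes: solution status is ", sol$status)
  ref <- sol$fluxes[[reference_reaction]]
  assert(abs(ref) > 1e-9,
         "reference flux ", reference_reaction, " is ~0 (", format(ref),
         "); relative fluxes are undefined, report absolute fluxes instead")
  sol$fluxes / abs(ref) * 100
}

#' Snapshot pFBA simulation of a fermentation time course
#'
#' Each phase is treated independently (a pseudo-steady-state snapshot):
#' the model is constrained with that phase's measured rates, growth is
#' maximized, and the parsimonious flux distribution recorded together
#' with the predicted specific growth rate, CO2 evolution rate and
#' relative fluxes (per 100 mol glucose uptake). An infeasible phase is
#' reported as such without aborting the remaining phases.
#'
#' @param model An `fx_model` with a biomass reaction.
#' @param phases List of [phase_constraints()] objects (may be empty).
#' @param map Rate mapping, see [default_exchange_map()].
#' @param pfba Use parsimonious FBA (default) or plain FBA.
#' @return List of per-phase results (class `fx_phase_result`): fields
#'   `constraints`, `solution`, `mu_predicted`, `qCO2_predicted`,
#'   `relative_fluxes`.
#' @export
simulate_phases <- function(model, phases, map = default_exchange_map(model),
                            pfba = TRUE) {
  assert(!is.na(model$biomass_reaction_id), "model declares no biomass reaction")
  model$objective <- setNames(1, model$biomass_reaction_id)
  lapply(phases, function(pc) {
    constrained <- apply_phase_constraints(model, pc, map)
    sol <- if (pfba) solve_pfba(constrained) else solve_fba(constrained)
    out <- list(constraints = pc, solution = sol,
                mu_predicted = NA_real_, qCO2_predicted = NA_real_,
                relative_fluxes = NULL)
    if (sol$status == "optimal") {
      out$mu_predicted <- sol$fluxes[[model$biomass_reaction_id]]
      out$qCO2_predicted <- sol$fluxes[[map$q_CO2]]
      out$relative_fluxes <- compute_relative_flux(sol, map$q_S)
    }
    structure(out, class = "fx_phase_result")
  })
}

#' Compare predicted growth and CO2 rates with measurements
#'
#' @param results Output of [simulate_phases()].
#' @param measured Data frame with columns `time_h`, `mu`, `qCO2`
#'   (q_CO2 as a positive magnitude).
#' @return List with a per-phase data frame (absolute and relative errors
#'   for mu and q_CO2) and summary means of the relative errors.
#' @export
validate_predictions <- function(results, measured) {
  pred_t <- vapply(results, function(r) r$constraints$time_h, 0)
  miss <- setdiff(round(pred_t, 6), round(measured$time_h, 6))
  extra <- setdiff(round(measured$time_h, 6), round(pred_t, 6))
  assert(length(miss) == 0L && length(extra) == 0L,
         "phase keys do not match; unmatched times: ",
         paste(c(miss, extra), collapse = ", "))
  idx <- match(round(pred_t, 6), round(measured$time_h, 6))
  rel_err <- function(pred, meas) {
    ae <- abs(pred - meas)
    ifelse(abs(meas) > 1e-12, ae / abs(meas), ifelse(ae < 1e-12, 0, Inf))
  }
  mu_meas <- measured$mu[idx]
  qc_meas <- abs(measured$qCO2[idx])
  mu_pred <- vapply(results, `[[`, 0, "mu_predicted")
  qc_pred <- abs(vapply(results, `[[`, 0, "qCO2_predicted"))
  tab <- data.frame(
    time_h = pred_t,
    mu_predicted = mu_pred, mu_measured = mu_meas,
    mu_abs_error = abs(mu_pred - mu_meas),
    mu_rel_error = rel_err(mu_pred, mu_meas),
    qCO2_predicted = qc_pred, qCO2_measured = qc_meas,
    qCO2_abs_error = abs(qc_pred - qc_meas),
    qCO2_rel_error = rel_err(qc_pred, qc_meas))
  list(per_phase = tab,
       mean_rel_error_mu = mean(tab$mu_rel_error, na.rm = TRUE),
       mean_rel_error_qCO2 = mean(tab$qCO2_rel_error, na.rm = TRUE))
}

#' Read / write a phase-constraint table
#'
#' TSV with columns `time_h, q_S, q_O2, q_P, m_ATP, tolerance` plus one
#' column per by-product exchange id.
#'
#' @param path File path.
#' @return List of [phase_constraints()].
#' @export
read_phase_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  fixed <- c("time_h", "q_S", "q_O2", "q_P", "m_ATP", "tolerance")
  assert(all(c("time_h", "q_S", "q_O2") %in% names(tab)),
         "phase table needs at least time_h, q_S, q_O2 columns")
  bp_cols <- setdiff(names(tab), fixed)
  lapply(seq_len(nrow(tab)), function(i) {
    phase_constraints(
      time_h = tab$time_h[i], q_S = tab$q_S[i], q_O2 = tab$q_O2[i],
      q_P = if ("q_P" %in% names(tab)) tab$q_P[i] else 0,
      q_byproducts = setNames(as.numeric(tab[i, bp_cols]), bp_cols),
      m_ATP = if ("m_ATP" %in% names(tab)) tab$m_ATP[i] else 0,
      tolerance = if ("tolerance" %in% names(tab)) tab$tolerance[i] else 0.05)
  })
}

#' @rdname read_phase_table
#' @param phases List of [phase_constraints()].
#' @export
write_phase_table <- function(phases, path) {
  bp_ids <- unique(unlist(lapply(phases, function(p) names(p$q_byproducts))))
  rows <- lapply(phases, function(p) {
    bp <- setNames(rep(0, length(bp_ids)), bp_ids)
    bp[names(p$q_byproducts)] <- p$q_byproducts
    c(time_h = p$time_h, q_S = p$q_S, q_O2 = p$q_O2, q_P = p$q_P,
      m_ATP = p$m_ATP, tolerance = p$tolerance, bp)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
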