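# Synthetic-data generators: toy metabolic networks with provable optima,
# a declarative fed-batch scenario with an oxygen-limitation switch, and
# omics matrices with planted structure. Every generator is a pure
# function of (parameters, seed).

#' Glucoamylase amino-acid composition
#'
#' The bundled composition table of the secreted product protein
#' (mass percent per amino acid, free-amino-acid molar mass, and the
#' lumped precursor family used by the toy network: pyruvate/3PG -> pyr,
#' oxaloacetate/2-oxoglutarate -> oaa, pentose/aromatic -> p5p).
#'
#' @return Data frame with `amino_acid`, `mass_percent`, `mw`,
#'   `precursor`, and derived `mole_fraction`.
#' @export
glucoamylase_composition <- function() {
  path <- system.file("extdata", "glucoamylase_aa_composition.tsv",
                      package = "fluxomix", mustWork = TRUE)
  tab <- read.delim(path)
  mol <- tab$mass_percent / tab$mw
  tab$mole_fraction <- mol / sum(mol)
  tab
}

# per-residue precursor demand of the product drain, from the composition
protein_precursor_demand <- function() {
  comp <- glucoamylase_composition()
  stats::setNames(
    vapply(c("pyr", "oaa", "p5p"),
           function(cl) sum(comp$mole_fraction[comp$precursor == cl]), 0),
    c("pyr", "oaa", "p5p"))
}

#' Mean residue molar mass of the product protein (g/mol)
#'
#' Used to convert a gravimetric secretion rate (g/gDCW/h) into the
#' mmol-residue/gDCW/h units of the product drain flux.
#' @export
glucoamylase_residue_mass <- function() {
  comp <- glucoamylase_composition()
  sum(comp$mole_fraction * (comp$mw - 18.02))   # peptide bond releases water
}

#' Build a toy metabolic model
#'
#' Three variants with hand-checkable optima:
#' * `chain` — uptake, conversion, secretion; the FBA optimum equals the
#'   uptake bound.
#' * `diamond` — two routes of equal yield (2 vs 3 reactions) between
#'   substrate and product; the FBA optimal face is degenerate and pFBA
#'   must pick the short route.
#' * `core` — a lumped central-carbon network: glucose uptake, EMP
#'   glycolysis, pentose-phosphate shunt (NADPH source), pyruvate
#'   dehydrogenase, a fully oxidative TCA lump (4 NADH + 1 ATP per
#'   acetyl-CoA), a glyoxylate bypass (oxaloacetate from 2 acetyl-CoA at
#'   only 1 NADH), oxidative phosphorylation (P/O = 2), a reduced
#'   by-product (polyol) outlet that reoxidizes NADH at a carbon cost,
#'   ATP maintenance, biomass, and a glucoamylase drain whose precursor
#'   stoichiometry follows the bundled amino-acid composition. The yields
#'   are chosen so that tightening the oxygen uptake bound provably moves
#'   oxaloacetate supply from the TCA side to the glyoxylate bypass and
#'   raises the EMP share of glucose.
#'
#' @param variant `"chain"`, `"diamond"` or `"core"`.
#' @return A validated `fx_model`.
#' @export
make_toy_model <- function(variant = c("core", "chain", "diamond")) {
  variant <- match.arg(variant)
  switch(variant, chain = toy_chain(), diamond = toy_diamond(),
         core = toy_core())
}

toy_chain <- function() {
  mets <- list(metabolite("a[e]", compartment = "e"),
               metabolite("b[e]", compartment = "e"))
  rxns <- list(
    reaction("EX_a", c("a[e]" = -1), lower_bound = -10, upper_bound = 0,
             reversible = TRUE),
    reaction("CONV", c("a[e]" = -1, "b[e]" = 1), 0, 1000),
    reaction("EX_b", c("b[e]" = -1), 0, 1000))
  metabolic_model(mets, rxns, objective = c(EX_b = 1), id = "toy_chain")
}

toy_diamond <- function() {
  mets <- c(lapply(c("a[e]", "b[e]"), function(i) metabolite(i, compartment = "e")),
            lapply(c("m1[c]", "m2[c]", "m3[c]"), metabolite))
  rxns <- list(
    reaction("EX_a", c("a[e]" = -1), -10, 0, reversible = TRUE),
    reaction("P1_1", c("a[e]" = -1, "m1[c]" = 1), 0, 1000),
    reaction("P1_2", c("m1[c]" = -1, "b[e]" = 1), 0, 1000),
    reaction("P2_1", c("a[e]" = -1, "m2[c]" = 1), 0, 1000),
    reaction("P2_2", c("m2[c]" = -1, "m3[c]" = 1), 0, 1000),
    reaction("P2_3", c("m3[c]" = -1, "b[e]" = 1), 0, 1000),
    reaction("EX_b", c("b[e]" = -1), 0, 1000))
  metabolic_model(mets, rxns, objective = c(EX_b = 1), id = "toy_diamond")
}

toy_core <- function() {
  ext <- c("glc[e]", "o2[e]", "co2[e]", "prot[e]", "pol[e]", "x[e]")
  cyt <- c("g6p[c]", "pyr[c]", "accoa[c]", "oaa[c]", "p5p[c]", "atp[c]",
           "nadh[c]", "nadph[c]", "co2[c]", "o2[c]")
  mets <- c(lapply(ext, function(i) metabolite(i, compartment = "e")),
            lapply(cyt, metabolite))
  prec <- protein_precursor_demand()
  genes <- paste0("orf", sprintf("%02d", 1:12))
  rxns <- list(
    reaction("EX_glc", c("glc[e]" = -1), -10, 0, reversible = TRUE),
    reaction("EX_o2", c("o2[e]" = -1), -1000, 0, reversible = TRUE),
    reaction("EX_co2", c("co2[e]" = -1), 0, 1000),
    reaction("EX_prot", c("prot[e]" = -1), 0, 1000),
    reaction("EX_pol", c("pol[e]" = -1), 0, 1000),
    reaction("EX_x", c("x[e]" = -1), 0, 1000),
    reaction("GLCt", c("glc[e]" = -1, "atp[c]" = -1, "g6p[c]" = 1), 0, 1000,
             gene_association = "orf01", subsystem = "transport"),
    reaction("O2t", c("o2[e]" = -1, "o2[c]" = 1), 0, 1000,
             subsystem = "transport"),
    reaction("CO2t", c("co2[c]" = -1, "co2[e]" = 1), 0, 1000,
             subsystem = "transport"),
    reaction("EMP", c("g6p[c]" = -1, "pyr[c]" = 2, "atp[c]" = 2, "nadh[c]" = 2),
             0, 1000, gene_association = "orf02 and orf03", subsystem = "EMP"),
    reaction("PP", c("g6p[c]" = -1, "p5p[c]" = 1, "nadph[c]" = 2, "co2[c]" = 1),
             0, 1000, gene_association = "orf04", subsystem = "PP"),
    # non-oxidative PP lump (transketolase/transaldolase): returns pentose
    # carbon to glycolysis so the oxidative branch can run for NADPH alone
    reaction("TKT", c("p5p[c]" = -1.2, "g6p[c]" = 1), -1000, 1000,
             reversible = TRUE, gene_association = "orf04", subsystem = "PP"),
    reaction("PDH", c("pyr[c]" = -1, "accoa[c]" = 1, "co2[c]" = 1, "nadh[c]" = 1),
             0, 1000, gene_association = "orf05 and orf06", subsystem = "EMP"),
    reaction("TCA", c("accoa[c]" = -1, "co2[c]" = 2, "nadh[c]" = 4, "atp[c]" = 1),
             0, 1000, gene_association = "orf07", subsystem = "TCA"),
    reaction("GLYOX", c("accoa[c]" = -2, "oaa[c]" = 1, "nadh[c]" = 1),
             0, 1000, gene_association = "orf08 or orf09", subsystem = "glyoxylate"),
    reaction("OXPHOS", c("nadh[c]" = -1, "o2[c]" = -0.5, "atp[c]" = 2),
             0, 1000, gene_association = "orf10", subsystem = "oxphos"),
    reaction("POLS", c("pyr[c]" = -1, "nadh[c]" = -1, "pol[e]" = 1),
             0, 1000, gene_association = "orf11", subsystem = "overflow"),
    reaction("ATPM", c("atp[c]" = -1), 0, 1000, subsystem = "maintenance"),
    # futile-cycle/uncoupling outlet: without it a measured q_O2 applied as
    # an equality over-determines the ATP balance
    reaction("ATPD", c("atp[c]" = -1), 0, 1000, subsystem = "dissipation"),
    reaction("PROT_SYN",
             c("pyr[c]" = -unname(prec[["pyr"]]),
               "oaa[c]" = -unname(prec[["oaa"]]),
               "p5p[c]" = -unname(prec[["p5p"]]),
               "atp[c]" = -4.3, "nadph[c]" = -1.5, "prot[e]" = 1),
             0, 1000, gene_association = "orf12", subsystem = "product"),
    reaction("BIOMASS",
             c("pyr[c]" = -1.0, "oaa[c]" = -0.6, "p5p[c]" = -0.25,
               "accoa[c]" = -0.3, "atp[c]" = -100, "nadph[c]" = -5,
               "x[e]" = 1),
             0, 1000, subsystem = "biomass"))
  metabolic_model(mets, rxns, genes = genes,
                  objective = c(BIOMASS = 1),
                  biomass_reaction_id = "BIOMASS",
                  atp_maintenance_reaction_id = "ATPM",
                  id = "toy_core")
}

#' Random small network for solver-vs-oracle checks
#'
#' Draws a random sparse stoichiometric system over a handful of internal
#' metabolites plus a few boundary (single-entry) reactions, with mixed
#' reversible/irreversible bounds. The zero flux vector is always
#' feasible and all bounds are finite, so the LP is bounded — suitable
#' for exhaustive vertex enumeration.
#'
#' @param n_mets Number of internal metabolites.
#' @param n_rxns Total reactions (<= 12 keeps enumeration fast).
#' @param seed RNG seed.
#' @return A validated `fx_model` with a random single-reaction objective.
#' @export
make_random_network <- function(n_mets = 4, n_rxns = 9, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n_ext <- 3L
  ext_ids <- paste0("x", seq_len(n_ext), "[e]")
  int_ids <- paste0("m", seq_len(n_mets), "[c]")
  mets <- c(lapply(ext_ids, function(i) metabolite(i, compartment = "e")),
            lapply(int_ids, metabolite))
  all_ids <- c(ext_ids, int_ids)
  rxns <- list()
  for (j in seq_len(n_ext))   # boundary reactions
    rxns[[j]] <- reaction(paste0("EX_", j), setNames(-1, ext_ids[[j]]),
                          lower_bound = -10, upper_bound = 10, reversible = TRUE)
  for (j in seq(n_ext + 1L, n_rxns)) {
    deg <- sample(2:3, 1)
    ids <- sample(all_ids, deg)
    coef <- sample(c(-2, -1, 1, 2), deg, replace = TRUE)
    if (all(coef > 0)) coef[1] <- -coef[1]
    if (all(coef < 0)) coef[1] <- -coef[1]
    rev <- runif(1) < 0.4
    rxns[[j]] <- reaction(paste0("R", j), setNames(coef, ids),
                          lower_bound = if (rev) -10 else 0, upper_bound = 10,
                          reversible = rev)
  }
  obj_rxn <- sample(seq_len(n_rxns), 1)
  metabolic_model(mets, rxns,
                  objective = setNames(1, rxns[[obj_rxn]]$id),
                  id = sprintf("random_%d", seed))
}

#' Declarative fed-batch scenario
#'
#' Specific-rate schedules for a fed-batch culture that switches from the
#' aerobic phase into oxygen limitation at `switch_time`: before the
#' switch the oxygen and glucose uptake rates are at their aerobic
#' plateaus; after it both drop sharply (the oxygen uptake about
#' 3.5-fold) and decay slowly, while the product drain is held at a
#' measured secretion level that rises under limitation.
#'
#' @param time_grid Sampling times (h).
#' @param switch_time Oxygen-limitation onset (h).
#' @param noise_sd Relative (multiplicative Gaussian) noise on emitted
#'   measured rates.
#' @param seed RNG seed used when noise is added.
#' @param tolerance Tolerance written into the emitted phase constraints;
#'   defaults to `2 * noise_sd` so the band covers ~95% of the
#'   measurement scatter it emulates (and collapses to equalities when
#'   the noise is off).
#' @return A list of class `fx_scenario` with rate functions and
#'   parameters.
#' @export
fermentation_scenario <- function(time_grid = c(18, 24, 36, 48, 60, 72),
                                  switch_time = 20, noise_sd = 0.05,
                                  seed = 1, tolerance = 2 * noise_sd) {
  rate <- function(aerobic, limited, decay) {
    force(aerobic); force(limited); force(decay)
    function(t) ifelse(t < switch_time, aerobic,
                       limited * exp(-decay * (t - switch_time)))
  }
  structure(list(
    time_grid = time_grid, switch_time = switch_time,
    q_S = rate(2.0, 1.0, 0.012),
    q_O2 = rate(5.0, 1.4, 0.012),
    q_P = rate(0.04, 0.08, 0),
    m_ATP = function(t) rep(0.8, length(t)),
    noise_sd = noise_sd, seed = seed, tolerance = tolerance),
    class = "fx_scenario")
}

#' Simulate a fermentation time course from the scenario
#'
#' For each time point the toy model is constrained exactly (zero
#' tolerance) with the scenario's true q_S, q_O2, q_P and m_ATP, growth
#' is maximized by pFBA, and the resulting flux vector is taken as the
#' ground truth. The emitted "measured" phase constraints carry
#' multiplicative Gaussian noise; the returned `measured` table carries
#' the TRUE growth and CO2 rates for prediction validation.
#'
#' @param model The `core` toy model (or any model exposing the default
#'   exchange map).
#' @param scenario A [fermentation_scenario()].
#' @return List: `phases` (noisy [phase_constraints()]), `measured`
#'   (data frame time_h, mu, qCO2), `true_fluxes` (list of named flux
#'   vectors), `true_rates` (data frame of the noise-free rates).
#' @export
simulate_fermentation <- function(model, scenario) {
  map <- default_exchange_map(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(scenario$seed)
  noisy <- function(x) x * exp(rnorm(length(x), 0, scenario$noise_sd))
  phases <- list(); fluxes <- list()
  measured <- true_rates <- NULL
  for (t in scenario$time_grid) {
    truth <- phase_constraints(t, q_S = scenario$q_S(t),
                               q_O2 = scenario$q_O2(t),
                               q_P = scenario$q_P(t),
                               m_ATP = scenario$m_ATP(t), tolerance = 0)
    sol <- solve_pfba(apply_phase_constraints(model, truth, map))
    assert(sol$status == "optimal",
           "scenario rates infeasible in the model at t=", t,
           " (q_S=", truth$q_S, ", q_O2=", truth$q_O2, ")")
    v <- sol$fluxes
    bp <- setNames(max(0, v[["EX_pol"]]), "EX_pol")
    phases[[length(phases) + 1L]] <- phase_constraints(
      t, q_S = noisy(truth$q_S), q_O2 = noisy(truth$q_O2),
      q_P = noisy(truth$q_P), q_byproducts = noisy(bp),
      m_ATP = noisy(truth$m_ATP), tolerance = scenario$tolerance)
    fluxes[[length(fluxes) + 1L]] <- v
    measured <- rbind(measured, data.frame(
      time_h = t, mu = v[[model$biomass_reaction_id]],
      qCO2 = v[[map$q_CO2]]))
    true_rates <- rbind(true_rates, data.frame(
      time_h = t, q_S = truth$q_S, q_O2 = truth$q_O2, q_P = truth$q_P,
      m_ATP = truth$m_ATP, q_pol = unname(bp)))
  }
  list(phases = phases, measured = measured, true_fluxes = fluxes,
       true_rates = true_rates)
}

#' Synthetic metabolite pool table with planted q_O2 trackers
#'
#' Informative metabolites vary log-linearly with the standardized oxygen
#' uptake rate (slope = `effect`); a second planted block accumulates (or
#' depletes) steadily with fermentation time, emulating the organic acids
#' that keep rising through the limited phase while most pools drop at
#' the switch; the rest are lognormal noise. Samples follow the pool
#' sampling grid with replicates and fall into three phase groups
#' (aerobic / early-limited / late-limited).
#'
#' @param n_metab Total metabolites.
#' @param n_informative Number of planted q_O2-tracking metabolites.
#' @param n_trend Number of planted time-trending metabolites.
#' @param time_grid,n_reps Sampling design.
#' @param effect Log-scale slope against the standardized covariate.
#' @param noise_sd Log-scale noise sd.
#' @param scenario Scenario providing the q_O2 schedule.
#' @param seed RNG seed.
#' @return List: `table` (an `fx_pool_table`), `q_O2` per sample,
#'   `informative` (ids of the q_O2 trackers), `trend` (ids of the time
#'   trenders), `group` (3-level factor per sample).
#' @export
make_synthetic_pools <- function(n_metab = 50, n_informative = 5, n_trend = 5,
                                 time_grid = c(18, 24, 36, 48, 60, 72, 96),
                                 n_reps = 2, effect = 0.8, noise_sd = 0.1,
                                 scenario = fermentation_scenario(), seed = 1) {
  assert(n_informative + n_trend <= n_metab, "planted blocks exceed n_metab")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  times <- rep(time_grid, each = n_reps)
  reps <- rep(seq_len(n_reps), length(time_grid))
  q <- scenario$q_O2(times)
  z <- as.vector(scale(q))
  group <- cut(times, c(-Inf, scenario$switch_time, 48, Inf),
               labels = c("aerobic", "limited_early", "limited_late"))
  # stepwise accumulation: one level per phase group, so the planted
  # sample grouping is a real three-level structure, not a smooth ramp
  zt <- as.vector(scale(as.numeric(group)))
  ids <- sprintf("met%02d", seq_len(n_metab))
  base <- exp(rnorm(n_metab, mean = 1, sd = 0.8))   # umol/gDCW scale spread
  X <- matrix(0, n_metab, length(times), dimnames = list(ids, NULL))
  trend_idx <- n_informative + seq_len(n_trend)
  for (i in seq_len(n_metab)) {
    # trend block alternates direction: half accumulate over the
    # fermentation (organic acids), half deplete (most pools)
    signal <- if (i <= n_informative) effect * z
      else if (i %in% trend_idx) effect * zt * c(-1, 1)[1 + i %% 2]
      else 0
    X[i, ] <- base[i] * exp(signal + rnorm(length(times), 0, noise_sd))
  }
  list(table = pool_table(X, time_h = times, replicate = reps),
       q_O2 = q, informative = ids[seq_len(n_informative)],
       trend = ids[trend_idx], group = group)
}

#' Synthetic expression matrix with planted patterns and gene sets
#'
#' Genes follow one of four temporal patterns (up, down, transient, flat)
#' on the FPKM scale with multiplicative lognormal noise; an extra block
#' of weakly expressed genes is planted for the low-expression filter.
#' Planted gene sets (all-up, all-down, mixed, null) exercise the
#' directional gene-set classes.
#'
#' @param n_per_pattern Genes per temporal pattern.
#' @param n_low Planted low-expression genes.
#' @param time_grid Expression sampling times (h).
#' @param n_reps Replicates per time point.
#' @param noise_sd Log-scale noise sd.
#' @param set_size Genes per planted set.
#' @param seed RNG seed.
#' @return List: `matrix` (an `fx_expr` with phase labels), `sets` (GMT
#'   list), `truth` (per-gene pattern, expected set calls, low ids).
#' @export
make_synthetic_expression <- function(n_per_pattern = 50, n_low = 20,
                                      time_grid = c(16, 24, 42, 66),
                                      n_reps = 2, noise_sd = 0.2,
                                      set_size = 25, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  profiles <- list(up = c(20, 60, 180, 400),
                   down = c(400, 180, 60, 20),
                   transient = c(30, 300, 300, 30),
                   flat = c(150, 150, 150, 150))
  assert(length(time_grid) == 4L, "pattern means are defined on 4 time points")
  patt <- rep(names(profiles), each = n_per_pattern)
  ids <- sprintf("gene%04d", seq_along(patt))
  times <- rep(time_grid, each = n_reps)
  reps <- rep(seq_len(n_reps), length(time_grid))
  X <- t(vapply(seq_along(patt), function(i) {
    mu <- profiles[[patt[i]]][match(times, time_grid)]
    mu * exp(rnorm(length(times), 0, noise_sd))
  }, numeric(length(times))))
  rownames(X) <- ids
  if (n_low > 0) {
    low_ids <- sprintf("lowg%03d", seq_len(n_low))
    low_mu <- c(0.2, 0.5, 0.3, 0.2)[match(times, time_grid)]
    L <- t(vapply(seq_len(n_low), function(i)
      low_mu * exp(rnorm(length(times), 0, noise_sd)), numeric(length(times))))
    rownames(L) <- low_ids
    X <- rbind(X, L)
  } else low_ids <- character()
  phase <- ifelse(times <= min(time_grid), "aerobic", "limited")
  mat <- expression_matrix(X, time_h = times, replicate = reps, phase = phase)

  up_ids <- ids[patt == "up"]; dn_ids <- ids[patt == "down"]
  fl_ids <- ids[patt == "flat"]; tr_ids <- ids[patt == "transient"]
  k <- min(set_size, n_per_pattern)
  sets <- list(
    set_all_up = up_ids[seq_len(k)],
    set_all_down = dn_ids[seq_len(k)],
    set_mixed = c(up_ids[seq(n_per_pattern - floor(k / 2) + 1, n_per_pattern)],
                  dn_ids[seq(n_per_pattern - ceiling(k / 2) + 1, n_per_pattern)]),
    set_null = fl_ids[seq_len(k)])
  truth <- list(pattern = setNames(patt, ids), low = low_ids,
                expected = c(set_all_up = "distinct_up",
                             set_all_down = "distinct_down",
                             set_mixed = "mixed_both",
                             set_null = "none"),
                transient = tr_ids)
  list(matrix = mat, sets = sets, truth = truth)
}
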