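# Orchestration: run the flux, metabolomics and transcriptomics stages
# from one configuration, write per-stage result tables, and join the
# per-phase story into a single integrative summary, with a JSON manifest
# recording configuration, seeds and output hashes. Stages are
# independent libraries; the "integration" is a join on identifiers and
# phases, mirroring how the flux shifts, metabolite screen and gene-set
# calls are read side by side.

#' Default pipeline configuration
#'
#' @param output_dir Where result tables are written.
#' @param seed Master seed, recorded and used for every stochastic step.
#' @return Nested configuration list; any entry can be overridden via
#'   [run_pipeline()]'s `config` argument.
#' @export
default_config <- function(output_dir = "fluxomix_results", seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    flux = list(enabled = TRUE, model = NULL, phases = NULL, measured = NULL,
                pfba = TRUE),
    metabolome = list(enabled = TRUE, pools = NULL, response = NULL,
                      n_components = 2, transform = "none",
                      scale = "autoscale"),
    transcriptome = list(enabled = TRUE, expression = NULL,
                         sample_sheet = NULL, gmt = NULL,
                         fpkm_threshold = 1, min_low_timepoints = 2,
                         k = 4, m = NULL, n_perm = 1999,
                         phase_a = "aerobic", phase_b = "limited",
                         vip_alpha = 0.05))
}

load_if_path <- function(x, loader, ...) {
  if (is.character(x) && length(x) == 1L) loader(x, ...) else x
}

stage_log <- function(...) message("[fluxomix] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (flux simulation, metabolomics,
#' transcriptomics), writes per-stage TSV outputs plus an integrative
#' per-phase summary and a JSON manifest (configuration echo, seed,
#' package version, md5 of every output). A failing stage is logged and
#' recorded; independent stages still run, and the integrative summary
#' covers whatever succeeded.
#'
#' @param config List as from [default_config()]; entries may be file
#'   paths (loaded with the package readers) or in-memory objects.
#' @return Invisibly, a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  errors <- list()
  results <- list()
  emit <- function(tab, name) {
    path <- file.path(cfg$output_dir, name)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stage_log("stage '", name, "' failed: ", conditionMessage(e))
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # validate configured paths up front, before any computation
  for (stage in c("flux", "metabolome", "transcriptome")) {
    if (!isTRUE(cfg[[stage]]$enabled)) next
    for (field in intersect(names(cfg[[stage]]),
                            c("model", "phases", "pools", "expression",
                              "sample_sheet", "gmt", "measured"))) {
      x <- cfg[[stage]][[field]]
      if (is.character(x) && length(x) == 1L)
        assert(file.exists(x), "configured ", stage, "$", field,
               " does not exist: ", x, class = "fluxomix_config_error")
    }
  }

  ## flux stage -----------------------------------------------------------
  if (isTRUE(cfg$flux$enabled)) results$flux <- run_stage("flux", function() {
    stage_log("flux: constraining and solving per phase")
    model <- load_if_path(cfg$flux$model, read_model)
    assert(!is.null(model), "flux stage enabled but no model given",
           class = "fluxomix_config_error")
    phases <- load_if_path(cfg$flux$phases, read_phase_table)
    assert(!is.null(phases), "flux stage enabled but no phases given",
           class = "fluxomix_config_error")
    res <- simulate_phases(model, phases, pfba = isTRUE(cfg$flux$pfba))
    flux_tab <- do.call(rbind, lapply(res, function(r) {
      if (r$solution$status != "optimal")
        return(data.frame(time_h = r$constraints$time_h, reaction = NA,
                          flux = NA, relative_flux = NA,
                          status = r$solution$status))
      data.frame(time_h = r$constraints$time_h,
                 reaction = names(r$solution$fluxes),
                 flux = unname(r$solution$fluxes),
                 relative_flux = unname(r$relative_fluxes),
                 status = "optimal")
    }))
    emit(flux_tab, "fluxes.tsv")
    validation <- NULL
    if (!is.null(cfg$flux$measured)) {
      measured <- load_if_path(cfg$flux$measured, read.delim)
      validation <- validate_predictions(res, measured)
      emit(validation$per_phase, "flux_validation.tsv")
    }
    list(results = res, validation = validation)
  })

  ## metabolome stage -----------------------------------------------------
  if (isTRUE(cfg$metabolome$enabled))
    results$metabolome <- run_stage("metabolome", function() {
      stage_log("metabolome: preprocessing, PCA, PLS-VIP screen")
      pools <- load_if_path(cfg$metabolome$pools, read_pool_table)
      assert(!is.null(pools), "metabolome stage enabled but no pools given",
             class = "fluxomix_config_error")
      y <- cfg$metabolome$response
      assert(!is.null(y), "metabolome stage needs a response (q_O2 per sample)",
             class = "fluxomix_config_error")
      prep <- preprocess_pools(pools, transform = cfg$metabolome$transform,
                               scale = cfg$metabolome$scale)
      pca <- run_pca(prep)
      emit(data.frame(sample = rownames(pca$scores),
                      time_h = prep$samples$time_h, pca$scores),
           "pca_scores.tsv")
      A <- cfg$metabolome$n_components %||%
        choose_ncomp_q2(t(prep$values), y)$n_components
      pls <- fit_pls(t(prep$values), y, n_components = A)
      vip <- compute_vip(pls)
      emit(data.frame(metabolite = names(vip$vip), vip = unname(vip$vip),
                      selected = unname(vip$selected)), "vip.tsv")
      ord <- heatmap_order(prep)
      list(pca = pca, pls = pls, vip = vip, heatmap = ord,
           n_components = A)
    })

  ## transcriptome stage --------------------------------------------------
  if (isTRUE(cfg$transcriptome$enabled))
    results$transcriptome <- run_stage("transcriptome", function() {
      tc <- cfg$transcriptome
      stage_log("transcriptome: filter, cluster, differential stats, GSA")
      mat <- if (is.character(tc$expression))
        read_expression(tc$expression, tc$sample_sheet) else tc$expression
      assert(!is.null(mat), "transcriptome stage enabled but no expression given",
             class = "fluxomix_config_error")
      sets <- load_if_path(tc$gmt, read_gmt)
      filt <- filter_low_expression(mat, tc$fpkm_threshold,
                                    tc$min_low_timepoints)
      prof <- standardize_profiles(filt)
      m_fuzz <- tc$m %||% estimate_fuzzifier(prof)
      fcm <- fuzzy_cmeans(prof, k = tc$k, m = m_fuzz,
                          seed = derive_seed(cfg$seed, 11))
      emit(data.frame(gene = rownames(prof),
                      cluster = unname(fcm$assignment),
                      membership = apply(fcm$memberships, 1, max)),
           "clusters.tsv")
      stats <- differential_stats(mat, tc$phase_a, tc$phase_b)
      emit(stats, "gene_stats.tsv")
      gsa <- ora <- NULL
      if (!is.null(sets)) {
        gsa <- gene_set_analysis(stats, sets, n_perm = tc$n_perm,
                                 seed = derive_seed(cfg$seed, 13))
        emit(gsa, "gsa.tsv")
        selected <- stats$gene[stats$p_value < 0.05 & !is.na(stats$p_value)]
        ora <- ora_hypergeometric(selected, stats$gene, sets)
        emit(ora, "ora.tsv")
      }
      list(filtered = filt, clustering = fcm, stats = stats, gsa = gsa,
           ora = ora, fuzzifier = m_fuzz)
    })

  ## integrative summary --------------------------------------------------
  if (!is.null(results$flux)) {
    key_paths <- c("EMP", "PP", "TCA", "GLYOX")
    summ <- do.call(rbind, lapply(results$flux$results, function(r) {
      if (r$solution$status != "optimal") return(NULL)
      rf <- r$relative_fluxes
      data.frame(time_h = r$constraints$time_h,
                 mu = r$mu_predicted, qCO2 = r$qCO2_predicted,
                 t(rf[intersect(key_paths, names(rf))]))
    }))
    if (!is.null(summ)) {
      if (!is.null(results$metabolome))
        summ$n_vip_selected <- sum(results$metabolome$vip$selected)
      if (!is.null(results$transcriptome) && !is.null(results$transcriptome$gsa)) {
        g <- results$transcriptome$gsa
        summ$n_sets_dist_up <- sum(g$q_dist_up < 0.05)
        summ$n_sets_dist_dn <- sum(g$q_dist_dn < 0.05)
      }
      emit(summ, "integration.tsv")
    }
  }

  manifest <- list(
    package = "fluxomix",
    version = as.character(utils::packageVersion("fluxomix")),
    r_version = R.version.string,
    seed = cfg$seed,
    stages_run = names(results),
    stages_failed = errors,
    config = rapply(cfg, function(x)
      if (is.function(x) || is.list(x)) NULL else x, how = "replace"),
    outputs = lapply(setNames(nm = outputs), function(p)
      unname(tools::md5sum(p))))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (length(errors))
    stage_log("completed with ", length(errors), " failed stage(s): ",
              paste(names(errors), collapse = ", "))
  invisible(c(results, list(manifest = manifest)))
}
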