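# Data structures for constraint-based metabolic models: metabolites,
# reactions with bounds and gene-protein-reaction (GPR) rules, and the
# stoichiometric matrix S used by every flux computation.

DEFAULT_UB <- 1000   # mmol/gDCW/h, conventional open bound
DEFAULT_LB <- -1000

#' Create a metabolite
#'
#' @param id Unique metabolite identifier (non-empty string).
#' @param name Human-readable name.
#' @param compartment Compartment token, e.g. `"c"` (cytosol), `"m"`
#'   (mitochondrion), `"e"` (extracellular).
#' @param formula Optional elemental formula string.
#' @return A list of class `fx_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_) {
  assert(is.character(id) && length(id) == 1L && nzchar(id),
         "metabolite id must be a non-empty string")
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula),
            class = "fx_metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative for consumed
#' (substrate), positive for produced (product). Bounds are in
#' mmol/gDCW/h; the biomass reaction flux is the specific growth rate in
#' 1/h.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds. Defaults follow the usual
#'   convention: irreversible reactions get `(0, 1000)`, reversible ones
#'   `(-1000, 1000)`.
#' @param reversible Logical; if bounds are supplied it is inferred as
#'   `lower_bound < 0`.
#' @param name Free-text name.
#' @param gene_association GPR boolean expression over gene ids, e.g.
#'   `"(g1 and g2) or g3"`. Empty string means spontaneous/unannotated.
#' @param subsystem Optional pathway label.
#' @return A list of class `fx_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = NULL, upper_bound = NULL,
                     reversible = NULL, name = id, gene_association = "",
                     subsystem = NA_character_) {
  assert(is.character(id) && length(id) == 1L && nzchar(id),
         "reaction id must be a non-empty string")
  assert(is.numeric(stoichiometry) && length(stoichiometry) > 0L &&
           !is.null(names(stoichiometry)) && all(nzchar(names(stoichiometry))),
         "stoichiometry must be a non-empty named numeric vector (reaction ", id, ")")
  assert(all(is.finite(stoichiometry)) && all(stoichiometry != 0),
         "stoichiometric coefficients must be finite and non-zero (reaction ", id, ")")
  if (is.null(reversible)) {
    reversible <- if (is.null(lower_bound)) FALSE else lower_bound < 0
  }
  if (is.null(lower_bound)) lower_bound <- if (reversible) DEFAULT_LB else 0
  if (is.null(upper_bound)) upper_bound <- DEFAULT_UB
  assert(lower_bound <= upper_bound,
         "lower_bound > upper_bound in reaction ", id)
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 reversible = isTRUE(reversible),
                 gene_association = gene_association,
                 subsystem = subsystem),
            class = "fx_reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param genes Character vector of gene/ORF ids.
#' @param objective Named numeric vector, reaction id -> objective
#'   coefficient (the `C` vector of the FBA objective `Z = C'v`).
#' @param biomass_reaction_id,atp_maintenance_reaction_id Ids of the
#'   biomass (growth) and non-growth ATP maintenance reactions, or `NA`.
#' @param compartments Declared compartment tokens; inferred from the
#'   metabolites when omitted.
#' @param id Model identifier.
#' @param validate Run structural validation (strict). Set `FALSE` only
#'   for models known to carry dangling references.
#' @return A list of class `fx_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective = numeric(),
                            biomass_reaction_id = NA_character_,
                            atp_maintenance_reaction_id = NA_character_,
                            compartments = NULL, id = "model",
                            validate = TRUE) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  if (is.null(compartments))
    compartments <- unique(vapply(metabolites, `[[`, "", "compartment"))
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions, genes = genes,
                          objective = objective,
                          biomass_reaction_id = biomass_reaction_id,
                          atp_maintenance_reaction_id = atp_maintenance_reaction_id,
                          compartments = compartments),
                     class = "fx_model")
  if (validate) validate_model(model)
  model
}

#' Structurally validate a model
#'
#' Checks uniqueness of ids, that every stoichiometric reference resolves,
#' that GPR genes are declared, that the objective and the named biomass /
#' maintenance reactions exist, and bound sanity.
#'
#' @param model An `fx_model`.
#' @param strict If `FALSE`, dangling metabolite/gene references are
#'   reported as warnings instead of errors.
#' @return The model, invisibly, on success.
#' @export
validate_model <- function(model, strict = TRUE) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  assert(!anyDuplicated(met_ids), "duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  assert(!anyDuplicated(rxn_ids), "duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  comp <- vapply(model$metabolites, `[[`, "", "compartment")
  bad_comp <- setdiff(unique(comp), model$compartments)
  assert(length(bad_comp) == 0L,
         "metabolite compartments not declared: ", paste(bad_comp, collapse = ", "))

  complain <- if (strict) abort else function(...) warning(paste0(...), call. = FALSE)
  dangling <- character()
  bad_genes <- character()
  for (r in model$reactions) {
    miss <- setdiff(names(r$stoichiometry), met_ids)
    if (length(miss)) dangling <- c(dangling, paste0(r$id, ":", miss))
    assert(r$lower_bound <= r$upper_bound, "lower_bound > upper_bound in ", r$id)
    if (nzchar(r$gene_association)) {
      g <- gpr_genes(parse_gpr(r$gene_association))
      bad <- setdiff(g, model$genes)
      if (length(bad)) bad_genes <- c(bad_genes, paste0(r$id, ":", bad))
    }
  }
  if (length(dangling))
    complain("dangling metabolite references: ", paste(dangling, collapse = ", "))
  if (length(bad_genes))
    complain("undeclared genes in GPR rules: ", paste(bad_genes, collapse = ", "))

  bad_obj <- setdiff(names(model$objective), rxn_ids)
  assert(length(bad_obj) == 0L,
         "objective references unknown reactions: ", paste(bad_obj, collapse = ", "))
  for (field in c("biomass_reaction_id", "atp_maintenance_reaction_id")) {
    rid <- model[[field]]
    if (!is.na(rid))
      assert(rid %in% rxn_ids, field, " '", rid, "' not found in model")
  }
  invisible(model)
}

#' Which reactions are exchanges?
#'
#' An exchange (boundary) pseudo-reaction has exactly one non-zero
#' stoichiometric entry, on a metabolite in an extracellular compartment.
#' Its flux is the specific uptake (negative) or secretion (positive) rate.
#'
#' @param model An `fx_model`.
#' @param extracellular Compartment tokens counted as extracellular.
#' @return Named logical vector over reaction ids.
#' @export
is_exchange_reaction <- function(model, extracellular = c("e", "extracellular")) {
  comp <- vapply(model$metabolites, `[[`, "", "compartment")
  vapply(model$reactions, function(r) {
    length(r$stoichiometry) == 1L &&
      comp[[names(r$stoichiometry)]] %in% extracellular
  }, logical(1))
}

#' Build the stoichiometric matrix S
#'
#' Row i / column j holds the coefficient of metabolite i in reaction j, so
#' the steady-state mass balance reads `S %*% v = 0`.
#'
#' @param model A validated `fx_model`.
#' @return A list of class `fx_stoich` with a sparse `values` matrix
#'   (`Matrix::dgCMatrix`), `row_index` (metabolite ids) and `col_index`
#'   (reaction ids). A model with zero metabolites yields a degenerate
#'   `0 x n` matrix with attribute `degenerate = TRUE`.
#' @export
build_stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)))
  out <- structure(list(values = S, row_index = met_ids, col_index = rxn_ids),
                   class = "fx_stoich")
  attr(out, "degenerate") <- length(met_ids) == 0L
  out
}

n_reactions <- function(model) length(model$reactions)
n_metabolites <- function(model) length(model$metabolites)

reaction_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  list(lb = lb, ub = ub)
}

#' @export
print.fx_model <- function(x, ...) {
  cat(sprintf("<fx_model '%s'>  %d metabolites, %d reactions, %d genes\n",
              x$id, n_metabolites(x), n_reactions(x), length(x$genes)))
  if (length(x$objective))
    cat("  objective:", paste(sprintf("%+g %s", x$objective, names(x$objective)),
                              collapse = " "), "\n")
  invisible(x)
}

#' Replace bounds on one reaction
#'
#' @param model An `fx_model`.
#' @param reaction_id Reaction to change.
#' @param lb,ub New bounds (either may be `NULL` to keep the current one).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  assert(reaction_id %in% names(model$reactions),
         "unknown reaction: ", reaction_id)
  r <- model$reactions[[reaction_id]]
  if (!is.null(lb)) r$lower_bound <- as.numeric(lb)
  if (!is.null(ub)) r$upper_bound <- as.numeric(ub)
  assert(r$lower_bound <= r$upper_bound,
         "bounds cross (lb > ub) for reaction ", reaction_id)
  model$reactions[[reaction_id]] <- r
  model
}
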