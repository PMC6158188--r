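# Model serialization.
#
# Two dialects:
#  * "tsv"  — a single plain-text file with [metabolites] / [reactions] /
#    [genes] sections and `key: value` header lines. Metabolite ids carry a
#    compartment suffix in square brackets (glc[e], atp[c]); reaction
#    equations are written `2 A[c] + B[c] -> C[c]`, with `<=>` marking
#    reversible reactions. Missing bounds default to (0, 1000) for
#    irreversible and (-1000, 1000) for reversible reactions.
#  * "sbml" — SBML Level 3 with the fbc conventions (flux bounds as
#    parameters, GPR as fbc:geneProductAssociation, objective as
#    fbc:listOfObjectives). The bracket suffix is folded into the species'
#    compartment attribute and restored on read.

#' Read a metabolic model
#'
#' @param path File path.
#' @param format `"tsv"` or `"sbml"`; guessed from the extension when
#'   omitted (`.xml`/`.sbml` -> sbml).
#' @param validate Passed to [metabolic_model()].
#' @return An `fx_model`.
#' @export
read_model <- function(path, format = NULL, validate = TRUE) {
  assert(file.exists(path), "model file not found: ", path, class = "fluxomix_io_error")
  format <- format %||%
    (if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) "sbml" else "tsv")
  switch(match.arg(format, c("tsv", "sbml")),
         tsv = read_model_tsv(path, validate = validate),
         sbml = read_model_sbml(path, validate = validate))
}

#' Write a metabolic model
#'
#' `read_model(write_model(m, p), p)` reproduces `m` field-for-field
#' (bounds, stoichiometry, canonical GPR strings).
#'
#' @param model An `fx_model`.
#' @param path Output path.
#' @param format `"tsv"` or `"sbml"` (guessed from extension when omitted).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- format %||%
    (if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) "sbml" else "tsv")
  switch(match.arg(format, c("tsv", "sbml")),
         tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

## ---------------------------------------------------------------- TSV ----

format_equation <- function(r) {
  st <- r$stoichiometry
  term <- function(ids) {
    coefs <- abs(st[ids])
    paste(ifelse(coefs == 1, ids, paste(format(coefs, scientific = FALSE,
                                               trim = TRUE), ids)),
          collapse = " + ")
  }
  lhs <- term(names(st)[st < 0])
  rhs <- term(names(st)[st > 0])
  arrow <- if (r$reversible) "<=>" else "->"
  paste(lhs, arrow, rhs)
}

parse_equation <- function(eq, line_no = NA) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  assert(length(sides) == 2L,
         "cannot parse reaction equation (line ", line_no, "): '", eq, "'",
         class = "fluxomix_parse_error")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    assert(!grepl("(^\\+)|(\\+\\s*$)|(\\+\\s*\\+)", side),
           "dangling '+' in equation (line ", line_no, "): '", eq, "'",
           class = "fluxomix_parse_error")
    out <- numeric()
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
      assert(nzchar(term), "empty term in equation (line ", line_no, "): '",
             eq, "'", class = "fluxomix_parse_error")
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[[1]]))
        assert(is.finite(coef), "bad coefficient '", parts[[1]],
               "' (line ", line_no, ")", class = "fluxomix_parse_error")
        out[parts[[2]]] <- sign * coef
      } else if (length(parts) == 1L) {
        out[parts[[1]]] <- sign
      } else {
        abort("cannot parse term '", term, "' (line ", line_no, ")",
              class = "fluxomix_parse_error")
      }
    }
    out
  }
  lhs <- parse_side(sides[[1]], -1)
  rhs <- parse_side(sides[[2]], +1)
  st <- numeric()
  for (m in names(lhs)) st[m] <- lhs[[m]]
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
  st[st != 0]
}

write_model_tsv <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# fluxomix model tsv v1")
  w("model_id: ", model$id)
  if (!is.na(model$biomass_reaction_id)) w("biomass: ", model$biomass_reaction_id)
  if (!is.na(model$atp_maintenance_reaction_id))
    w("atp_maintenance: ", model$atp_maintenance_reaction_id)
  if (length(model$objective))
    w("objective: ", paste(sprintf("%s=%.17g", names(model$objective),
                                   model$objective), collapse = ","))
  w("compartments: ", paste(model$compartments, collapse = ","))
  w("")
  w("[metabolites]")
  w("id\tname\tcompartment\tformula")
  for (m in model$metabolites)
    w(m$id, "\t", m$name, "\t", m$compartment, "\t",
      ifelse(is.na(m$formula), "", m$formula))
  w("")
  w("[reactions]")
  w("id\tname\tequation\tlb\tub\tgpr\tsubsystem")
  for (r in model$reactions)
    w(r$id, "\t", r$name, "\t", format_equation(r), "\t",
      sprintf("%.17g", r$lower_bound), "\t", sprintf("%.17g", r$upper_bound),
      "\t", r$gene_association, "\t", ifelse(is.na(r$subsystem), "", r$subsystem))
  w("")
  w("[genes]")
  w("id")
  for (g in model$genes) w(g)
  invisible(path)
}

read_model_tsv <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  header <- list(model_id = "model", objective = "", compartments = NULL,
                 biomass = NA_character_, atp_maintenance = NA_character_)
  section <- NULL
  mets <- list(); rxns <- list(); genes <- character()
  met_cols <- rxn_cols <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*(#|$)", ln)) next
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]\\s*$", "\\1", ln)
      assert(section %in% c("metabolites", "reactions", "genes"),
             "unknown section '", section, "' at line ", i,
             class = "fluxomix_parse_error")
      met_cols <- rxn_cols <- NULL  # next non-blank line is the header row
      next
    }
    if (is.null(section)) {
      kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
      assert(length(kv) == 3L, "cannot parse header line ", i, ": '", ln, "'",
             class = "fluxomix_parse_error")
      header[[kv[[2]]]] <- kv[[3]]
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "metabolites") {
      if (is.null(met_cols)) { met_cols <- fields; next }
      fields <- c(fields, rep("", length(met_cols) - length(fields)))
      names(fields) <- met_cols
      mets[[length(mets) + 1L]] <- metabolite(
        id = fields[["id"]], name = fields[["name"]],
        compartment = fields[["compartment"]],
        formula = if (nzchar(fields[["formula"]])) fields[["formula"]] else NA_character_)
    } else if (section == "reactions") {
      if (is.null(rxn_cols)) { rxn_cols <- fields; next }
      fields <- c(fields, rep("", length(rxn_cols) - length(fields)))
      names(fields) <- rxn_cols
      st <- parse_equation(fields[["equation"]], line_no = i)
      rev <- grepl("<=>", fields[["equation"]], fixed = TRUE)
      lb <- if (nzchar(fields[["lb"]])) as.numeric(fields[["lb"]]) else NULL
      ub <- if (nzchar(fields[["ub"]])) as.numeric(fields[["ub"]]) else NULL
      rxns[[length(rxns) + 1L]] <- reaction(
        id = fields[["id"]], name = fields[["name"]], stoichiometry = st,
        lower_bound = lb, upper_bound = ub, reversible = rev,
        gene_association = fields[["gpr"]],
        subsystem = if (nzchar(fields[["subsystem"]])) fields[["subsystem"]] else NA_character_)
    } else if (section == "genes") {
      if (identical(fields[[1]], "id")) next
      genes <- c(genes, fields[[1]])
    }
  }
  obj <- numeric()
  if (nzchar(header$objective)) {
    for (pair in strsplit(header$objective, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
      obj[trimws(kv[[1]])] <- as.numeric(kv[[2]])
    }
  }
  comps <- if (!is.null(header$compartments))
    trimws(strsplit(header$compartments, ",")[[1]]) else NULL
  metabolic_model(mets, rxns, genes = genes, objective = obj,
                  biomass_reaction_id = header$biomass,
                  atp_maintenance_reaction_id = header$atp_maintenance,
                  compartments = comps, id = header$model_id,
                  validate = validate)
}

## --------------------------------------------------------------- SBML ----

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# `glc[e]` -> list(base = "glc", comp = "e"); plain ids keep comp = NA
split_met_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\[([^]]+)\\]$", id))[[1]]
  if (length(m) == 3L) list(base = m[[2]], comp = m[[3]])
  else list(base = id, comp = NA_character_)
}

sid_check <- function(x, what) {
  bad <- x[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)]
  assert(length(bad) == 0L, "ids not serializable as SBML SIds (", what, "): ",
         paste(bad, collapse = ", "), class = "fluxomix_io_error")
  x
}

write_model_sbml <- function(model, path) {
  met_ids <- names(model$metabolites)
  parts <- lapply(met_ids, split_met_id)
  bases <- vapply(parts, `[[`, "", "base")
  sid_check(bases, "metabolites")
  sid_check(names(model$reactions), "reactions")
  comps <- vapply(model$metabolites, `[[`, "", "compartment")
  met_sid <- setNames(paste0("M_", bases, "_", comps), met_ids)
  assert(!anyDuplicated(met_sid), "metabolite ids collide after SBML mangling",
         class = "fluxomix_io_error")

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sid_check(model$id, "model"),
                               "fbc:strict" = "false")
  comp_node <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cmp in model$compartments)
    xml2::xml_add_child(comp_node, "compartment", id = cmp, constant = "true")

  sp_node <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_along(model$metabolites)) {
    m <- model$metabolites[[i]]
    sp <- xml2::xml_add_child(sp_node, "species", id = met_sid[[m$id]],
                              name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    # remember whether the package-convention bracket suffix was present
    xml2::xml_set_attr(sp, "metaid",
                       if (is.na(parts[[i]]$comp)) "plain" else "bracket")
  }

  # distinct flux-bound values become shared parameters
  bounds <- reaction_bounds(model)
  all_b <- sort(unique(c(bounds$lb, bounds$ub)))
  bkey <- function(b) sprintf("%.17g", b)
  par_id <- setNames(sprintf("fb_%d", seq_along(all_b)), bkey(all_b))
  par_node <- xml2::xml_add_child(mnode, "listOfParameters")
  for (b in all_b)
    xml2::xml_add_child(par_node, "parameter",
                        id = par_id[[bkey(b)]],
                        value = sprintf("%.17g", b), constant = "true")

  rx_node <- xml2::xml_add_child(mnode, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rx_node, "reaction", id = paste0("R_", r$id),
                              name = r$name,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound", par_id[[bkey(r$lower_bound)]])
    xml2::xml_set_attr(rn, "fbc:upperFluxBound", par_id[[bkey(r$upper_bound)]])
    if (!is.na(r$subsystem)) xml2::xml_set_attr(rn, "metaid", r$subsystem)
    st <- r$stoichiometry
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(st)[st < 0])
        xml2::xml_add_child(lr, "speciesReference", species = met_sid[[m]],
                            stoichiometry = sprintf("%.17g", -st[[m]]),
                            constant = "true")
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(st)[st > 0])
        xml2::xml_add_child(lp, "speciesReference", species = met_sid[[m]],
                            stoichiometry = sprintf("%.17g", st[[m]]),
                            constant = "true")
    }
    tree <- parse_gpr(r$gene_association)
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpr_node <- function(parent, node) {
        if (node$op == "gene") {
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", node$gene)))
        } else {
          el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
          for (a in node$args) write_gpr_node(el, a)
        }
      }
      write_gpr_node(gpa, tree)
    }
  }

  if (length(model$genes)) {
    gp_node <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(gp_node, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", g)),
                          "fbc:label" = g)
  }

  if (length(model$objective)) {
    ob_node <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                                   "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(ob_node, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective))
      xml2::xml_add_child(lfo, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", rid),
                          "fbc:coefficient" = sprintf("%.17g", model$objective[[rid]]))
  }

  # annotation block for package-level fields not covered by core SBML
  ann <- xml2::xml_add_child(mnode, "annotation")
  meta <- xml2::xml_add_child(ann, "fluxomixModelMeta")
  if (!is.na(model$biomass_reaction_id))
    xml2::xml_set_attr(meta, "biomass", model$biomass_reaction_id)
  if (!is.na(model$atp_maintenance_reaction_id))
    xml2::xml_set_attr(meta, "atpMaintenance", model$atp_maintenance_reaction_id)

  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path, validate = TRUE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    abort("malformed SBML in ", path, ": ", conditionMessage(e),
          class = "fluxomix_parse_error"))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, "./s:model", ns)
  assert(!inherits(mnode, "xml_missing"), "no <model> element in ", path,
         class = "fluxomix_parse_error")

  comps <- xml2::xml_attr(xml2::xml_find_all(mnode, ".//s:compartment", ns), "id")

  pars <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  par_val <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                      xml2::xml_attr(pars, "id"))

  gp_nodes <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- setNames(xml2::xml_attr(gp_nodes, "label"),
                         xml2::xml_attr(gp_nodes, "id"))
  genes <- unname(gene_label)

  sp_nodes <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  mets <- vector("list", length(sp_nodes))
  sid2id <- character()
  for (i in seq_along(sp_nodes)) {
    sp <- sp_nodes[[i]]
    sid <- xml2::xml_attr(sp, "id")
    comp <- xml2::xml_attr(sp, "compartment")
    base <- sub(paste0("_", comp, "$"), "", sub("^M_", "", sid))
    id <- if (identical(xml2::xml_attr(sp, "metaid"), "bracket"))
      paste0(base, "[", comp, "]") else base
    formula <- xml2::xml_attr(sp, "chemicalFormula")
    mets[[i]] <- metabolite(id = id, name = xml2::xml_attr(sp, "name"),
                            compartment = comp,
                            formula = if (is.na(formula)) NA_character_ else formula)
    sid2id[sid] <- id
  }

  read_gpr_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gp <- xml2::xml_attr(node, "geneProduct")
      return(list(op = "gene", gene = unname(gene_label[gp]) %||% sub("^G_", "", gp)))
    }
    list(op = nm, args = lapply(xml2::xml_children(node), read_gpr_node))
  }

  rxn_nodes <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  rxns <- vector("list", length(rxn_nodes))
  for (i in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[i]]
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      id <- sid2id[[xml2::xml_attr(sr, "species")]]
      st[id] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      id <- sid2id[[xml2::xml_attr(sr, "species")]]
      st[id] <- (st[id] %||% 0) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(st[id])) st[id] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    st <- st[st != 0 & !is.na(st)]
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      deparse_gpr(read_gpr_node(xml2::xml_child(gpa)))
    subsys <- xml2::xml_attr(rn, "metaid")
    rxns[[i]] <- reaction(
      id = sub("^R_", "", xml2::xml_attr(rn, "id")),
      name = xml2::xml_attr(rn, "name"), stoichiometry = st,
      lower_bound = unname(par_val[[xml2::xml_attr(rn, "lowerFluxBound")]]),
      upper_bound = unname(par_val[[xml2::xml_attr(rn, "upperFluxBound")]]),
      reversible = xml2::xml_attr(rn, "reversible") == "true",
      gene_association = gpr,
      subsystem = if (is.na(subsys)) NA_character_ else subsys)
  }

  obj <- numeric()
  for (fo in xml2::xml_find_all(mnode, ".//fbc:fluxObjective", ns))
    obj[sub("^R_", "", xml2::xml_attr(fo, "reaction"))] <-
      as.numeric(xml2::xml_attr(fo, "coefficient"))

  meta <- xml2::xml_find_first(mnode, ".//s:annotation/*", ns)
  biomass <- atpm <- NA_character_
  if (!inherits(meta, "xml_missing")) {
    biomass <- xml2::xml_attr(meta, "biomass")
    atpm <- xml2::xml_attr(meta, "atpMaintenance")
  }

  metabolic_model(mets, rxns, genes = genes, objective = obj,
                  biomass_reaction_id = biomass %||% NA_character_,
                  atp_maintenance_reaction_id = atpm %||% NA_character_,
                  compartments = comps, id = xml2::xml_attr(mnode, "id"),
                  validate = validate)
}
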