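## SBML Level 3 Version 1 + fbc v2 reader and writer, built on xml2.
##
## The reader understands the subset of SBML that genome-scale
## constraint-based models actually use: compartments, species with
## fbc charge/chemicalFormula, reactions with fbc flux-bound parameters
## and gene-product associations, the active fbc objective, and
## subsystem labels either in reaction notes ("SUBSYSTEM: ...") or in a
## groups:listOfGroups. Standard "M_"/"R_"/"G_" id prefixes are
## stripped on read and restored on write. Numeric values are written
## with 17 significant digits so a load/save/load round trip preserves
## stoichiometry and bounds bit-exactly.

.sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.sbml_groups_ns <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

.strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

.attr_ns <- function(node, name, prefixes) {
  for (p in prefixes) {
    v <- xml2::xml_attr(node, paste0(p, name))
    if (!is.na(v)) return(v)
  }
  xml2::xml_attr(node, name)
}

.ns_prefix_for <- function(doc, uri) {
  ns <- xml2::xml_ns(doc)
  hits <- names(ns)[ns == uri]
  if (!length(hits)) return(character(0))
  paste0(hits, ":")
}

#' Read an SBML Level 3 (fbc) model
#'
#' @param path path to an SBML file.
#' @return a [metabolic_model()].
#' @seealso [save_sbml()]
#' @export
load_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML XML in '", path, "': ", conditionMessage(e))
  })
  ns <- xml2::xml_ns(doc)
  if (!.sbml_core_ns %in% ns) {
    stop("not an SBML Level 3 Version 1 document: ", path)
  }
  core <- names(ns)[ns == .sbml_core_ns][1]
  fbcp <- .ns_prefix_for(doc, .sbml_fbc_ns)
  if (!length(fbcp)) {
    stop("unsupported dialect: SBML file lacks the fbc (flux bounds/objective) ",
         "extension required for constraint-based models: ", path)
  }
  q <- function(x) gsub("q:", paste0(core, ":"), x, fixed = TRUE)
  model_node <- xml2::xml_find_first(doc, q("./q:model"))
  if (inherits(model_node, "xml_missing")) stop("SBML parse error: no <model> element")

  comp_nodes <- xml2::xml_find_all(model_node, q("./q:listOfCompartments/q:compartment"))
  comps <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"), xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(model_node, q("./q:listOfSpecies/q:species"))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  raw_ids <- xml2::xml_attr(sp_nodes, "id")
  mets <- data.frame(
    id = .strip_prefix(raw_ids, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  .strip_prefix(raw_ids, "M_"), xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = vapply(sp_nodes, function(n) {
      v <- .attr_ns(n, "chemicalFormula", fbcp); if (is.na(v)) "" else v
    }, character(1)),
    charge = vapply(sp_nodes, function(n) {
      v <- .attr_ns(n, "charge", fbcp)
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  boundary_ids <- mets$id[boundary]
  mets <- mets[!boundary, , drop = FALSE]
  sp_map <- stats::setNames(mets$id, raw_ids[!boundary])

  par_nodes <- xml2::xml_find_all(model_node, q("./q:listOfParameters/q:parameter"))
  params <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(.strip_prefix(.attr_ns(node, "geneProduct", fbcp), "G_"))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  subsystem_from_notes <- function(rn) {
    notes <- xml2::xml_find_first(rn, q("./q:notes"))
    if (inherits(notes, "xml_missing")) return("")
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^\n]*", txt))
    if (!length(m)) return("")
    trimws(sub("SUBSYSTEM:\\s*", "", m))
  }

  rxn_nodes <- xml2::xml_find_all(model_node, q("./q:listOfReactions/q:reaction"))
  rxns <- lapply(rxn_nodes, function(rn) {
    rid_raw <- xml2::xml_attr(rn, "id")
    rid <- .strip_prefix(rid_raw, "R_")
    lb_id <- .attr_ns(rn, "lowerFluxBound", fbcp)
    ub_id <- .attr_ns(rn, "upperFluxBound", fbcp)
    if (is.na(lb_id) || is.na(ub_id)) {
      stop("unsupported dialect: reaction '", rid,
           "' has no fbc flux-bound attributes")
    }
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, q(paste0("./q:", side, "/q:speciesReference")))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      for (i in seq_along(sp)) {
        if (.strip_prefix(sp[i], "M_") %in% boundary_ids) next
        mid <- sp_map[[sp[i]]]
        st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + coef[i]
      }
    }
    gpa_node <- xml2::xml_find_first(
      rn, paste0("./*[local-name()='geneProductAssociation']"))
    rule <- if (inherits(gpa_node, "xml_missing")) "" else {
      kid <- xml2::xml_children(gpa_node)
      if (length(kid)) gpa_to_string(kid[[1]]) else ""
    }
    list(id = rid, stoichiometry = st,
         lb = params[[lb_id]], ub = params[[ub_id]],
         gene_rule = rule, subsystem = subsystem_from_notes(rn))
  })
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")

  ## subsystems from a groups package, if present (overrides empty notes)
  grp_nodes <- xml2::xml_find_all(
    model_node, "./*[local-name()='listOfGroups']/*[local-name()='group']")
  for (g in grp_nodes) {
    gname <- xml2::xml_attr(g, "name")
    if (is.na(gname)) next
    members <- xml2::xml_find_all(g, ".//*[local-name()='member']")
    for (mref in xml2::xml_attr(members, "idRef")) {
      rid <- .strip_prefix(mref, "R_")
      if (rid %in% names(rxns) && !nzchar(rxns[[rid]]$subsystem)) {
        rxns[[rid]]$subsystem <- gname
      }
    }
  }

  obj_ref <- xml2::xml_find_first(
    model_node,
    "./*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (inherits(obj_ref, "xml_missing")) {
    stop("unsupported dialect: no fbc objective found in ", path)
  }
  objective_id <- .strip_prefix(.attr_ns(obj_ref, "reaction", fbcp), "R_")

  metabolic_model(id = xml2::xml_attr(model_node, "id") %||% "model",
                  metabolites = mets, reactions = rxns,
                  objective_id = objective_id, compartments = comps)
}

## parse a boolean gene rule string into nested list AST
.parse_gene_rule <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    lhs <- parse_term()
    parts <- list(lhs)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); parts <- c(parts, list(parse_term()))
    }
    if (length(parts) == 1) parts[[1]] else list(op = "or", args = parts)
  }
  parse_term <- function() {
    lhs <- parse_factor()
    parts <- list(lhs)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); parts <- c(parts, list(parse_factor()))
    }
    if (length(parts) == 1) parts[[1]] else list(op = "and", args = parts)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene rule: '", rule, "'")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("malformed gene rule: '", rule, "'")
      return(e)
    }
    t
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("malformed gene rule: '", rule, "'")
  out
}

.gene_rule_ids <- function(rule) {
  if (!nzchar(trimws(rule))) return(character(0))
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  setdiff(toks, c("(", ")", "and", "or", "AND", "OR"))
}

.num17 <- function(x) sprintf("%.17g", x)

#' Write a model as SBML Level 3 (fbc v2)
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_sbml <- function(model, path) {
  root <- xml2::xml_new_root(
    "sbml", xmlns = .sbml_core_ns, "xmlns:fbc" = .sbml_fbc_ns,
    level = "3", version = "1", "fbc:required" = "false")
  mn <- xml2::xml_add_child(root, "model", id = model$id, "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (i in seq_along(model$compartments)) {
    xml2::xml_add_child(lc, "compartment", id = names(model$compartments)[i],
                        name = model$compartments[[i]], constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", m$id),
                              name = m$name, compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (nzchar(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    xml2::xml_set_attr(sp, "fbc:charge", as.character(as.integer(m$charge)))
  }

  bounds <- unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub))))
  par_ids <- stats::setNames(paste0("fb_", seq_along(bounds)), .num17(bounds))
  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = par_ids[[i]],
                        value = .num17(bounds[i]), constant = "true",
                        sboTerm = "SBO:0000626")
  }

  genes <- unique(unlist(lapply(model$reactions, function(r) .gene_rule_ids(r$gene_rule))))
  if (length(genes)) {
    lg <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
    }
  }

  add_gpa <- function(parent, ast) {
    if (is.character(ast)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", ast))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
      for (a in ast$args) add_gpa(node, a)
    }
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", r$id),
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound", par_ids[[.num17(r$lb)]])
    xml2::xml_set_attr(rn, "fbc:upperFluxBound", par_ids[[.num17(r$ub)]])
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(reac)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", names(reac)[j]),
                            stoichiometry = .num17(-reac[[j]]), constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", names(prod)[j]),
                            stoichiometry = .num17(prod[[j]]), constant = "true")
      }
    }
    if (nzchar(trimws(r$gene_rule))) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_gpa(gpa, .parse_gene_rule(r$gene_rule))
    }
  }

  lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective_id),
                      "fbc:coefficient" = "1")

  xml2::write_xml(root, path)
  invisible(path)
}
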