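## JSON model dialect.
##
## Schema: top-level keys `id`, `compartments` (map code -> name),
## `metabolites` [{id,name,compartment,formula,charge}],
## `reactions` [{id,stoichiometry:{met:coeff},lb,ub,gene_rule,subsystem}],
## `objective`. Unknown top-level fields are preserved in the model's
## `extras` bag and written back on save; keys are emitted sorted so a
## load/save round trip is byte-identical.

.json_known_keys <- c("id", "compartments", "metabolites", "reactions", "objective")

#' Read a model from the JSON dialect
#'
#' @param path path to a JSON file following the documented schema.
#' @return a [metabolic_model()].
#' @seealso [save_json_model()]
#' @export
load_json_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("id", "metabolites", "reactions", "objective")) {
    if (is.null(doc[[key]])) stop("JSON model: missing required field '", key, "'")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    for (key in c("id", "compartment")) {
      if (is.null(m[[key]])) stop("JSON model: metabolite missing field '", key, "'")
    }
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% "",
               charge = as.numeric(m$charge %||% 0),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    for (key in c("id", "stoichiometry", "lb", "ub")) {
      if (is.null(r[[key]])) {
        stop("JSON model: reaction '", r$id %||% "?", "' missing field '", key, "'")
      }
    }
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         gene_rule = r$gene_rule %||% "",
         subsystem = r$subsystem %||% "")
  })
  comps <- if (!is.null(doc$compartments)) unlist(doc$compartments) else
    c(c = "cytosol", p = "periplasm", e = "extracellular")
  extras <- doc[setdiff(names(doc), .json_known_keys)]
  metabolic_model(id = doc$id, metabolites = mets, reactions = rxns,
                  objective_id = doc$objective, compartments = comps,
                  extras = extras)
}

#' Write a model in the JSON dialect
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_json_model <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(charge = m$charge, compartment = m$compartment,
         formula = m$formula, id = m$id, name = m$name)
  })
  rxns <- lapply(model$reactions, function(r) {
    st <- r$stoichiometry[order(names(r$stoichiometry))]
    list(gene_rule = r$gene_rule, id = r$id, lb = r$lb,
         stoichiometry = as.list(st), subsystem = r$subsystem, ub = r$ub)
  })
  doc <- c(list(compartments = as.list(model$compartments),
                id = model$id,
                metabolites = mets,
                objective = model$objective_id,
                reactions = unname(rxns)),
           model$extras)
  doc <- doc[order(names(doc))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
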