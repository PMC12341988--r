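#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a set of metabolites, a set of
#' bounded reactions, and a biomass objective. The stoichiometric matrix
#' is derived on demand with [stoich_matrix()].
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `name`,
#'   `compartment`, `formula`, `charge`.
#' @param reactions list of reactions; each a list with elements `id`,
#'   `stoichiometry` (named numeric, negative = consumed), `lb`, `ub`,
#'   `gene_rule` (string, possibly empty) and `subsystem`.
#' @param objective_id id of the objective (biomass) reaction.
#' @param compartments named character vector mapping compartment codes
#'   to names, e.g. `c(c = "cytosol", p = "periplasm", e = "extracellular")`.
#' @param extras free-form list preserved across JSON round trips.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective_id,
                            compartments = c(c = "cytosol", p = "periplasm",
                                             e = "extracellular"),
                            extras = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  need <- c("id", "name", "compartment", "formula", "charge")
  miss <- setdiff(need, names(metabolites))
  if (length(miss)) stop("metabolites lack column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metabolites$id)) {
    stop("duplicated metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  bad_cmp <- setdiff(unique(metabolites$compartment), names(compartments))
  if (length(bad_cmp)) stop("undeclared compartment(s): ", paste(bad_cmp, collapse = ", "))

  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(names(reactions))) stop("duplicated reaction ids")
  for (r in reactions) {
    if (!length(r$stoichiometry)) stop("reaction '", r$id, "' has empty stoichiometry")
    unknown <- setdiff(names(r$stoichiometry), metabolites$id)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "': lower bound exceeds upper bound")
  }
  if (!objective_id %in% names(reactions)) {
    stop("objective reaction '", objective_id, "' not in model")
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 objective_id = objective_id, compartments = compartments,
                 extras = extras),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", length(x$reactions),
      "   exchanges: ", sum(is_exchange(x)), "\n", sep = "")
  cat("  objective:   ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Reaction and metabolite ids
#' @param model a `metabolic_model`.
#' @return character vector of ids.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Which reactions are exchanges?
#'
#' A reaction is an exchange (boundary) reaction when it touches exactly
#' one metabolite: it moves mass across the model boundary.
#'
#' @param model a `metabolic_model`.
#' @return named logical vector over reactions.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoichiometry) == 1L, logical(1))
}

#' Dense stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return matrix with one row per metabolite and one column per
#'   reaction, dimnames set to the respective ids.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Flux bounds of all reactions
#' @param model a `metabolic_model`.
#' @return data frame with columns `reaction`, `lb`, `ub`.
#' @export
flux_bounds <- function(model) {
  data.frame(reaction = names(model$reactions),
             lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
             ub = vapply(model$reactions, `[[`, numeric(1), "ub"),
             row.names = NULL)
}

#' Update bounds of one reaction
#' @param model a `metabolic_model`.
#' @param reaction reaction id.
#' @param lb,ub new bounds (either may be `NULL` to keep the current one).
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction, lb = NULL, ub = NULL) {
  if (!reaction %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction)
  }
  if (!is.null(lb)) model$reactions[[reaction]]$lb <- lb
  if (!is.null(ub)) model$reactions[[reaction]]$ub <- ub
  if (model$reactions[[reaction]]$lb > model$reactions[[reaction]]$ub) {
    stop("reaction '", reaction, "': lower bound exceeds upper bound")
  }
  model
}

#' Number of reactions without a gene association
#' @param model a `metabolic_model`.
#' @return integer count of reactions whose `gene_rule` is empty.
#' @export
orphan_reaction_count <- function(model) {
  sum(vapply(model$reactions, function(r) {
    is.null(r$gene_rule) || is.na(r$gene_rule) || !nzchar(trimws(r$gene_rule))
  }, logical(1)))
}

#' Check elemental balance of all internal reactions
#'
#' For every non-exchange reaction the per-element imbalance
#' \eqn{\sum_i c_i n_{ie}} is computed from the metabolite formulas
#' (coefficient times element count, summed over participants). Reactions
#' touching a metabolite without a usable formula (missing, malformed, or
#' containing placeholder residues R/X) are skipped and listed as
#' warnings rather than reported as unbalanced.
#'
#' @param model a `metabolic_model`.
#' @param tol absolute imbalance below which an element is considered
#'   balanced.
#' @return an object of class `validation_report`: list with
#'   `unbalanced` (data frame `reaction`, `element`, `imbalance`),
#'   `skipped` (reactions excluded for missing formulas),
#'   `orphan_reaction_count`, and `exchange_ids`.
#' @export
validate_mass_balance <- function(model, tol = 1e-6) {
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  counts <- lapply(formulas, function(f) {
    if (has_placeholder(f)) NULL else parse_formula(f)
  })
  exch <- is_exchange(model)
  unbalanced <- list()
  skipped <- character(0)
  for (r in model$reactions[!exch]) {
    cs <- counts[names(r$stoichiometry)]
    if (any(vapply(cs, is.null, logical(1)))) {
      skipped <- c(skipped, r$id)
      next
    }
    imb <- numeric(0)
    for (i in seq_along(cs)) {
      v <- cs[[i]] * r$stoichiometry[i]
      for (el in names(v)) imb[el] <- (if (el %in% names(imb)) imb[el] else 0) + v[[el]]
    }
    imb <- imb[abs(imb) > tol]
    if (length(imb)) {
      unbalanced[[r$id]] <- data.frame(reaction = r$id, element = names(imb),
                                       imbalance = as.numeric(imb), row.names = NULL)
    }
  }
  unbalanced <- if (length(unbalanced)) do.call(rbind, unbalanced) else
    data.frame(reaction = character(0), element = character(0), imbalance = numeric(0))
  rownames(unbalanced) <- NULL
  structure(list(unbalanced = unbalanced, skipped = skipped,
                 orphan_reaction_count = orphan_reaction_count(model),
                 exchange_ids = names(model$reactions)[exch]),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  unbalanced internal reactions: ", length(unique(x$unbalanced$reaction)), "\n", sep = "")
  if (nrow(x$unbalanced)) {
    print(utils::head(x$unbalanced, 20))
  }
  cat("  skipped (missing/placeholder formulas): ", length(x$skipped), "\n", sep = "")
  cat("  reactions without gene association:     ", x$orphan_reaction_count, "\n", sep = "")
  cat("  exchange reactions:                     ", length(x$exchange_ids), "\n", sep = "")
  invisible(x)
}

#' Write a validation report as TSV
#' @param report a `validation_report`.
#' @param path output file path or `""` for stdout.
#' @return the report, invisibly.
#' @export
write_validation_tsv <- function(report, path = "") {
  df <- report$unbalanced
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
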