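#' Maintenance specification
#'
#' Growth-associated maintenance (GAM) is an ATP cost embedded in the
#' biomass reaction, in mmol ATP per gDW of biomass formed (the 1/h
#' dimension enters through the growth rate). Non-growth-associated
#' maintenance (NGAM) is the lower bound of the ATP hydrolysis
#' maintenance reaction, in mmol ATP/gDW/h. The P/O ratio records the
#' ATP yield per oxygen atom assumed for the respiratory chain.
#'
#' @param gam mmol ATP per gDW biomass (default 10.86).
#' @param ngam mmol ATP/gDW/h (default 3.5).
#' @param po_ratio dimensionless ATP per O (default 2.5).
#' @return list of class `maintenance_spec`.
#' @export
maintenance_spec <- function(gam = 10.86, ngam = 3.5, po_ratio = 2.5) {
  stopifnot(gam >= 0, ngam >= 0, po_ratio > 0)
  structure(list(gam = gam, ngam = ngam, po_ratio = po_ratio),
            class = "maintenance_spec")
}

#' Growth condition
#'
#' A named bundle of exchange uptake bounds, ratio constraints,
#' reversibility overrides and maintenance settings describing one
#' simulated growth scenario. Uptake values are positive magnitudes;
#' they are applied as negative exchange lower bounds (uptake = negative
#' flux through an exchange reaction).
#'
#' @param name scenario name.
#' @param uptake_bounds named numeric vector, exchange id -> maximum
#'   uptake (mmol/gDW/h, nonnegative).
#' @param ratio_constraints list of [ratio_constraint()] objects.
#' @param reversible_overrides named list, reaction id -> `c(lb, ub)`.
#' @param maintenance a [maintenance_spec()] or `NULL` to leave the
#'   model's maintenance untouched.
#' @param close_other_uptakes logical; close every exchange uptake not
#'   named in `uptake_bounds` (default `TRUE`).
#' @return list of class `growth_condition`.
#' @export
condition <- function(name, uptake_bounds = numeric(0),
                      ratio_constraints = list(),
                      reversible_overrides = list(),
                      maintenance = NULL, close_other_uptakes = TRUE) {
  if (any(uptake_bounds < 0)) stop("uptake bounds must be nonnegative magnitudes")
  structure(list(name = name, uptake_bounds = uptake_bounds,
                 ratio_constraints = ratio_constraints,
                 reversible_overrides = reversible_overrides,
                 maintenance = maintenance,
                 close_other_uptakes = close_other_uptakes),
            class = "growth_condition")
}

#' Apply a condition to a model
#'
#' Returns a copy of the model with exchange bounds, reversibility
#' overrides and maintenance installed. Ratio constraints are *not*
#' baked into bounds; they stay on the condition and enter the LP as
#' equality rows.
#'
#' @param model a `metabolic_model`.
#' @param cond a [condition()].
#' @return the modified model.
#' @export
apply_condition <- function(model, cond) {
  if (!is.null(cond$maintenance)) {
    model <- set_maintenance(model, cond$maintenance)
  }
  exch <- names(model$reactions)[is_exchange(model)]
  if (isTRUE(cond$close_other_uptakes)) {
    for (rid in setdiff(exch, names(cond$uptake_bounds))) {
      model$reactions[[rid]]$lb <- max(model$reactions[[rid]]$lb, 0)
    }
  }
  unknown <- setdiff(names(cond$uptake_bounds), names(model$reactions))
  if (length(unknown)) {
    stop("condition '", cond$name, "' references unknown exchange(s): ",
         paste(unknown, collapse = ", "))
  }
  for (rid in names(cond$uptake_bounds)) {
    model$reactions[[rid]]$lb <- -cond$uptake_bounds[[rid]]
  }
  for (rid in names(cond$reversible_overrides)) {
    if (!rid %in% names(model$reactions)) {
      stop("reversibility override references unknown reaction: ", rid)
    }
    bb <- cond$reversible_overrides[[rid]]
    model$reactions[[rid]]$lb <- bb[1]
    model$reactions[[rid]]$ub <- bb[2]
  }
  model
}

## reactions that net-consume a metabolite matching `pattern`, excluding
## exchanges, pure transports and the biomass objective; used to build
## "total oxidation flux" denominators from stoichiometry.
.consumers_of <- function(model, pattern) {
  base <- function(ids) sub("_[a-z]$", "", ids)
  out <- character(0)
  exch <- is_exchange(model)
  for (r in model$reactions) {
    if (exch[[r$id]] || r$id == model$objective_id) next
    st <- r$stoichiometry
    cons <- names(st)[st < 0]
    prod <- names(st)[st > 0]
    hit <- grepl(pattern, cons)
    if (!any(hit)) next
    ## transport: the same base metabolite appears on both sides
    if (any(base(cons)[hit] %in% base(prod))) next
    out <- c(out, r$id)
  }
  unique(out)
}

#' Reactions oxidizing formaldehyde / hydrogen
#'
#' Finds the reactions that consume (and do not merely translocate)
#' formaldehyde or molecular hydrogen; these define the denominators of
#' the flux-split ratio constraints.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
formaldehyde_consumers <- function(model) .consumers_of(model, "^fald_")

#' @rdname formaldehyde_consumers
#' @export
h2_consumers <- function(model) .consumers_of(model, "^h2_")

.default_exchanges <- c(ch4 = "EX_ch4_e", o2 = "EX_o2_e", co2 = "EX_co2_e",
                        h2o = "EX_h2o_e", h = "EX_h_e", nh4 = "EX_nh4_e",
                        h2 = "EX_h2_e", propane = "EX_ppa_e",
                        isopropanol = "EX_ppoh_e", acetone = "EX_actn_e")

.carbon_count <- c(ch4 = 1, propane = 3, isopropanol = 3, acetone = 3)

#' Build a standard growth condition
#'
#' Constructs the conditions used throughout the analyses: substrate
#' uptake normalized to a fixed carbon uptake rate (uptake = carbon
#' uptake / carbon atoms per molecule), unconstrained O2, ammonium,
#' water and proton exchange, CO2 secretion open, and the default
#' flux-split constraints: for methane, 20% of formaldehyde oxidation
#' through the direct cytochrome-linked route; for autotrophic growth on
#' H2+CO2, 76% of H2 oxidation through the periplasmic hydrogenase with
#' complex I allowed to run in reverse.
#'
#' @param substrate one of `"ch4"`, `"h2_co2"`, `"propane"`,
#'   `"isopropanol"`, `"acetone"`.
#' @param carbon_uptake carbon uptake rate in C-mmol/gDW/h (default 3.5);
#'   ignored for `"h2_co2"`.
#' @param model optional `metabolic_model` used to derive the ratio
#'   denominators from stoichiometry; without it the canonical reaction
#'   ids of the bundled mini-model are used.
#' @param h2_uptake H2 uptake in mmol/gDW/h for autotrophic growth
#'   (default 13.2).
#' @param faldh_fraction share of formaldehyde oxidized by the direct
#'   cytochrome-coupled route (default 0.2); `NA` omits the constraint.
#' @param hyd_fraction share of H2 oxidized periplasmically
#'   (default 0.76); `NA` omits the constraint.
#' @param maintenance a [maintenance_spec()] (default `maintenance_spec()`)
#'   or `NULL`.
#' @param exchanges named map from substrate roles to exchange ids.
#' @return a [condition()].
#' @export
build_condition <- function(substrate, carbon_uptake = 3.5, model = NULL,
                            h2_uptake = 13.2, faldh_fraction = 0.2,
                            hyd_fraction = 0.76,
                            maintenance = maintenance_spec(),
                            exchanges = .default_exchanges) {
  substrate <- match.arg(substrate,
                         c("ch4", "h2_co2", "propane", "isopropanol", "acetone"))
  free <- c(o2 = 1000, nh4 = 1000, h2o = 1000, h = 1000)
  uptake <- stats::setNames(as.numeric(free), exchanges[names(free)])
  rcs <- list()
  overrides <- list()
  if (substrate == "h2_co2") {
    uptake[exchanges[["h2"]]] <- h2_uptake
    uptake[exchanges[["co2"]]] <- 1000
    if (!is.na(hyd_fraction)) {
      denom <- if (!is.null(model)) h2_consumers(model) else c("HYD4pp", "NAD_H2")
      rcs <- list(ratio_constraint("HYD4pp", denom, hyd_fraction))
    }
    overrides[["NADH16pp"]] <- c(-1000, 1000)
  } else {
    q <- carbon_uptake / .carbon_count[[substrate]]
    uptake[exchanges[[substrate]]] <- q
    if (substrate == "ch4" && !is.na(faldh_fraction)) {
      denom <- if (!is.null(model)) formaldehyde_consumers(model) else
        c("FALDHpp", "FALDTHF")
      rcs <- list(ratio_constraint("FALDHpp", denom, faldh_fraction))
    }
  }
  condition(name = substrate, uptake_bounds = uptake,
            ratio_constraints = rcs, reversible_overrides = overrides,
            maintenance = maintenance)
}

#' Read / write a condition as YAML
#'
#' The file either names a standard scenario (`substrate`,
#' `carbon_uptake`, optional `h2_uptake`, `gam`, `ngam`) or spells out
#' `uptake_bounds`, `ratio_constraints`
#' (list of `{focal, denominator, fraction}`), `reversible_overrides`
#' and maintenance directly.
#'
#' @param path YAML file path.
#' @param model optional model forwarded to [build_condition()].
#' @return a [condition()].
#' @export
read_condition_yaml <- function(path, model = NULL) {
  doc <- yaml::read_yaml(path)
  maint <- maintenance_spec(gam = doc$gam %||% 10.86, ngam = doc$ngam %||% 3.5,
                            po_ratio = doc$po_ratio %||% 2.5)
  if (!is.null(doc$substrate)) {
    return(build_condition(doc$substrate,
                           carbon_uptake = doc$carbon_uptake %||% 3.5,
                           model = model,
                           h2_uptake = doc$h2_uptake %||% 13.2,
                           faldh_fraction = doc$faldh_fraction %||% 0.2,
                           hyd_fraction = doc$hyd_fraction %||% 0.76,
                           maintenance = maint))
  }
  rcs <- lapply(doc$ratio_constraints, function(rc) {
    ratio_constraint(rc$focal, unlist(rc$denominator), rc$fraction)
  })
  overrides <- lapply(doc$reversible_overrides, function(b) as.numeric(unlist(b)))
  condition(name = doc$name %||% "condition",
            uptake_bounds = unlist(doc$uptake_bounds) %||% numeric(0),
            ratio_constraints = rcs %||% list(),
            reversible_overrides = overrides %||% list(),
            maintenance = maint)
}

#' @rdname read_condition_yaml
#' @param cond a [condition()] to serialize.
#' @export
write_condition_yaml <- function(cond, path) {
  doc <- list(name = cond$name,
              uptake_bounds = as.list(cond$uptake_bounds),
              ratio_constraints = lapply(cond$ratio_constraints, function(rc) {
                list(focal = rc$focal, denominator = rc$denominator,
                     fraction = rc$fraction)
              }),
              reversible_overrides = lapply(cond$reversible_overrides, as.list))
  if (!is.null(cond$maintenance)) {
    doc$gam <- cond$maintenance$gam
    doc$ngam <- cond$maintenance$ngam
    doc$po_ratio <- cond$maintenance$po_ratio
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
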