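#' Read standard reaction Gibbs energies from TSV
#'
#' Expected columns: `reaction_id`, `dg0_kj_mol` (standard reaction
#' Gibbs energy, kJ/mol), `sd_kj_mol` (its standard deviation).
#'
#' @param path TSV file path.
#' @return data frame with columns `reaction_id`, `dg0`, `sd`.
#' @export
read_gibbs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "dg0_kj_mol", "sd_kj_mol")
  if (!all(need %in% names(df))) {
    stop("Gibbs TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$sd_kj_mol < 0)) stop("negative standard deviation in Gibbs records")
  data.frame(reaction_id = df$reaction_id, dg0 = df$dg0_kj_mol,
             sd = df$sd_kj_mol, stringsAsFactors = FALSE)
}

#' Assign reaction directionality from Gibbs energies
#'
#' A reaction is made irreversible only when the thermodynamic signal is
#' both strong and precise: the standard reaction Gibbs energy must
#' exceed 1 kJ/mol in magnitude and its standard deviation must be below
#' 3% of that magnitude. Negative energies fix the forward direction
#' (lower bound 0); positive energies fix the reverse (upper bound 0);
#' anything else leaves the bounds untouched.
#'
#' @param model a `metabolic_model`.
#' @param gibbs data frame from [read_gibbs_tsv()] (columns
#'   `reaction_id`, `dg0`, `sd`).
#' @return the model with updated bounds.
#' @export
assign_directionality <- function(model, gibbs) {
  if (any(gibbs$sd < 0)) stop("negative standard deviation in Gibbs records")
  for (i in seq_len(nrow(gibbs))) {
    rid <- gibbs$reaction_id[i]
    if (!rid %in% names(model$reactions)) {
      warning("Gibbs record for unknown reaction '", rid, "' skipped")
      next
    }
    dg <- gibbs$dg0[i]; sd <- gibbs$sd[i]
    if (abs(dg) > 1 && sd < 0.03 * abs(dg)) {
      if (dg < 0) model$reactions[[rid]]$lb <- 0
      else model$reactions[[rid]]$ub <- 0
    }
  }
  model
}

#' Default energy-dissipation stoichiometries
#'
#' One dissipation reaction per energy metabolite, written in the
#' model's namespace: hydrolysis for the nucleoside triphosphates and
#' acetyl-CoA, electron release for the redox couples (NADH, NADPH,
#' FADH2, FMNH2 and menaquinol), and a periplasm-to-cytosol proton leak
#' for the transmembrane gradient. Entries whose metabolites are absent
#' from the model are dropped by the detector.
#'
#' @return named list of named numeric stoichiometries.
#' @export
energy_dissipation_reactions <- function() {
  ntp <- function(tp, dp) {
    stats::setNames(c(-1, -1, 1, 1, 1),
                    c(paste0(tp, "_c"), "h2o_c", paste0(dp, "_c"), "pi_c", "h_c"))
  }
  redox <- function(red, ox, nh) {
    stats::setNames(c(-1, 1, nh), c(red, ox, "h_c"))
  }
  list(
    atp = ntp("atp", "adp"), ctp = ntp("ctp", "cdp"), gtp = ntp("gtp", "gdp"),
    utp = ntp("utp", "udp"), itp = ntp("itp", "idp"),
    nadh = redox("nadh_c", "nad_c", 1),
    nadph = redox("nadph_c", "nadp_c", 1),
    fadh2 = redox("fadh2_c", "fad_c", 2),
    fmnh2 = redox("fmnh2_c", "fmn_c", 2),
    mql8 = redox("mql8_c", "mqn8_c", 2),
    accoa = stats::setNames(c(-1, -1, 1, 1, 1),
                            c("accoa_c", "h2o_c", "ac_c", "coa_c", "h_c")),
    h_gradient = stats::setNames(c(-1, 1), c("h_p", "h_c"))
  )
}

#' Detect energy-generating cycles
#'
#' For each energy metabolite a dissipation reaction is added, every
#' exchange is closed (zero bounds), and the dissipation flux is
#' maximized. A positive optimum means the network can generate the
#' energy carrier from nothing: an erroneous energy-generating cycle.
#' The participating reactions are taken from the parsimonious
#' dissipating flux distribution.
#'
#' @param model a `metabolic_model`.
#' @param dissipation named list of dissipation stoichiometries
#'   (default [energy_dissipation_reactions()]).
#' @param tol dissipation flux above which a cycle is reported.
#' @return list of reports, each with `energy_metabolite`,
#'   `dissipation_flux` and `cycle_reactions`; empty list if the model
#'   is cycle-free.
#' @export
detect_energy_generating_cycles <- function(model,
                                            dissipation = energy_dissipation_reactions(),
                                            tol = 1e-6) {
  closed <- model
  for (rid in names(closed$reactions)[is_exchange(closed)]) {
    closed$reactions[[rid]]$lb <- 0
    closed$reactions[[rid]]$ub <- 0
  }
  reports <- list()
  for (nm in names(dissipation)) {
    st <- dissipation[[nm]]
    missing <- setdiff(names(st), closed$metabolites$id)
    if (length(missing)) next
    test <- closed
    test$reactions[["DISSIP__"]] <- list(id = "DISSIP__", stoichiometry = st,
                                         lb = 0, ub = 1000, gene_rule = "",
                                         subsystem = "dissipation probe")
    lp <- .build_lp(test)
    obj <- as.numeric(lp$reactions == "DISSIP__")
    res <- lp_solve(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (res$status == "unbounded") {
      reports[[length(reports) + 1L]] <-
        list(energy_metabolite = nm, dissipation_flux = Inf,
             cycle_reactions = character(0))
      next
    }
    if (res$status == "optimal" && res$objective > tol) {
      lp2 <- lp; lp2$obj <- obj
      fl <- .pfba_stage(lp2, res$objective, 1e-9)
      members <- setdiff(names(fl)[abs(fl) > tol], "DISSIP__")
      reports[[length(reports) + 1L]] <-
        list(energy_metabolite = nm, dissipation_flux = res$objective,
             cycle_reactions = members)
    }
  }
  reports
}

.gam_currency <- c(atp = "atp_c", adp = "adp_c", pi = "pi_c",
                   h2o = "h2o_c", h = "h_c")

#' Normalize the biomass reaction to 1 g/mmol
#'
#' Rescales the biomass precursor coefficients by a single common factor
#' so that the summed precursor weight equals 1000 g/mol (i.e. 1 g of
#' biomass per mmol of biomass reaction flux). GAM currency metabolites
#' (ATP, ADP, phosphate, water, protons) are excluded from both the
#' weight sum and the scaling, so maintenance costs are untouched. If
#' the reaction produces a biomass pseudo-metabolite, its formula is
#' recomputed from the rescaled reaction so elemental balance is
#' preserved.
#'
#' @param model a `metabolic_model`.
#' @param target_weight target weight in g/mol (default 1000).
#' @param currency named map of currency metabolite ids.
#' @return the model with a rescaled biomass reaction.
#' @export
normalize_biomass <- function(model, target_weight = 1000,
                              currency = .gam_currency) {
  bio <- model$reactions[[model$objective_id]]
  st <- bio$stoichiometry
  is_product_pseudo <- st > 0 & grepl("biomass", names(st), ignore.case = TRUE)
  precursor <- names(st)[!(names(st) %in% currency) & !is_product_pseudo & st < 0]
  if (!length(precursor)) stop("biomass reaction has no precursor metabolites")
  mw <- vapply(precursor, function(mid) {
    f <- model$metabolites$formula[model$metabolites$id == mid]
    w <- molecular_weight(f)
    if (is.na(w)) stop("biomass precursor '", mid,
                       "' lacks a usable formula; cannot normalize")
    w
  }, numeric(1))
  total <- sum(abs(st[precursor]) * mw)
  factor <- target_weight / total
  st[precursor] <- st[precursor] * factor
  model$reactions[[model$objective_id]]$stoichiometry <- st
  ## keep the biomass pseudo-metabolite formula consistent
  pseudo <- names(st)[is_product_pseudo]
  if (length(pseudo) == 1) {
    counts <- numeric(0)
    formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
    ok <- TRUE
    for (mid in setdiff(names(st), pseudo)) {
      fc <- tryCatch(parse_formula(formulas[[mid]]), error = function(e) NULL)
      if (is.null(fc) || !length(fc)) { ok <- FALSE; break }
      v <- fc * (-st[[mid]])
      for (el in names(v)) counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + v[[el]]
    }
    if (ok) {
      model$metabolites$formula[model$metabolites$id == pseudo] <-
        format_formula(counts / st[[pseudo]])
    }
  }
  model
}

#' Install maintenance costs
#'
#' Adds `spec$gam` mmol ATP (+ water) per gDW to the biomass reaction,
#' producing matching ADP, phosphate and protons, and sets the lower
#' bound of the ATP maintenance reaction (`ATPM`, created if absent) to
#' `spec$ngam`. Re-applying with a different spec replaces the previous
#' GAM rather than accumulating it.
#'
#' @param model a `metabolic_model`.
#' @param spec a [maintenance_spec()].
#' @param currency named map of currency metabolite ids.
#' @return the modified model.
#' @export
set_maintenance <- function(model, spec, currency = .gam_currency) {
  missing <- setdiff(currency, model$metabolites$id)
  if (length(missing)) {
    stop("currency metabolite(s) absent from model: ",
         paste(missing, collapse = ", "))
  }
  prev <- model$extras$gam_applied %||% 0
  delta <- spec$gam - prev
  st <- model$reactions[[model$objective_id]]$stoichiometry
  add <- stats::setNames(c(-delta, -delta, delta, delta, delta),
                         currency[c("atp", "h2o", "adp", "pi", "h")])
  for (mid in names(add)) {
    st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + add[[mid]]
  }
  model$reactions[[model$objective_id]]$stoichiometry <- st[abs(st) > 1e-12]
  model$extras$gam_applied <- spec$gam
  if (!"ATPM" %in% names(model$reactions)) {
    model$reactions[["ATPM"]] <- list(
      id = "ATPM",
      stoichiometry = stats::setNames(c(-1, -1, 1, 1, 1),
                                      currency[c("atp", "h2o", "adp", "pi", "h")]),
      lb = 0, ub = 1000, gene_rule = "", subsystem = "Biomass and maintenance")
  }
  model$reactions[["ATPM"]]$lb <- spec$ngam
  model
}

#' Growth yields from a flux solution
#'
#' Yields are referenced to the substrate uptake: \eqn{Y_{O2} =
#' |v_{O2}|/q_S}, \eqn{Y_{CO2} = v_{CO2}/q_S}, and the biomass carbon
#' yield \eqn{Y_X = (\mu \cdot 1000 / w_{Cmol}) / q_S} in C-mol per mol,
#' using a biomass formula weight of `cmol_weight` g per C-mol.
#'
#' @param solution a `flux_solution`.
#' @param substrate_exchange exchange id of the carbon/energy substrate.
#' @param o2_exchange,co2_exchange exchange ids for O2 and CO2.
#' @param cmol_weight biomass formula weight, g per C-mol (default 24.6).
#' @return list of class `yield_set` with `mu`, `q_substrate`, `y_o2`,
#'   `y_co2`, `y_x`.
#' @export
compute_yields <- function(solution, substrate_exchange,
                           o2_exchange = "EX_o2_e", co2_exchange = "EX_co2_e",
                           cmol_weight = 24.6) {
  if (solution$status != "optimal") stop("solution is not optimal")
  q <- abs(solution$fluxes[[substrate_exchange]])
  if (q < 1e-9) stop("zero substrate uptake through ", substrate_exchange,
                     "; yields are undefined")
  mu <- solution$objective_value
  structure(list(mu = mu, q_substrate = q,
                 y_o2 = abs(solution$fluxes[[o2_exchange]]) / q,
                 y_co2 = max(solution$fluxes[[co2_exchange]], 0) / q,
                 y_x = (mu * 1000 / cmol_weight) / q),
            class = "yield_set")
}

#' @export
print.yield_set <- function(x, ...) {
  cat(sprintf("<yield_set> mu=%.4g 1/h  qS=%.4g  Y_O2=%.3g  Y_CO2=%.3g  Y_X=%.3g\n",
              x$mu, x$q_substrate, x$y_o2, x$y_co2, x$y_x))
  invisible(x)
}

#' Fit growth-associated maintenance to an oxygen yield
#'
#' Finds the GAM value whose simulated O2 yield matches a target
#' (typically an experimentally measured substrate:O2 ratio) by
#' bisection over `bracket`. The O2 yield is checked to be monotone over
#' the bracket ends; a target outside the attainable range is an error
#' reporting that range.
#'
#' @param model a `metabolic_model`.
#' @param cond a [condition()]; its maintenance NGAM and P/O are kept,
#'   GAM is varied.
#' @param target_y_o2 target O2 yield (mol/mol).
#' @param substrate_exchange exchange id of the substrate.
#' @param bracket search interval for GAM (default `c(0, 100)`).
#' @param tol bisection tolerance on GAM (default 0.01).
#' @return the fitted GAM (mmol ATP/gDW).
#' @export
fit_gam_to_yield <- function(model, cond, target_y_o2,
                             substrate_exchange, bracket = c(0, 100),
                             tol = 0.01) {
  eval_y <- function(g) {
    cond$maintenance <- maintenance_spec(gam = g, ngam = cond$maintenance$ngam,
                                         po_ratio = cond$maintenance$po_ratio)
    sol <- solve_fba(model, cond, solver_settings(parsimonious = TRUE))
    if (sol$status != "optimal") return(NA_real_)
    compute_yields(sol, substrate_exchange)$y_o2
  }
  lo <- bracket[1]; hi <- bracket[2]
  ylo <- eval_y(lo); yhi <- eval_y(hi)
  if (is.na(ylo)) stop("infeasible at GAM = ", lo)
  while (is.na(yhi)) {              # shrink until growth is feasible
    hi <- (lo + hi) / 2
    yhi <- eval_y(hi)
    if (hi - lo < tol) stop("infeasible over almost the whole bracket")
  }
  if (ylo > yhi) stop("O2 yield is not non-decreasing over the bracket")
  if (target_y_o2 < ylo - 0.01 || target_y_o2 > yhi + 0.01) {
    stop(sprintf("target Y_O2 %.3f outside attainable range [%.3f, %.3f]",
                 target_y_o2, ylo, yhi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    ymid <- eval_y(mid)
    if (is.na(ymid) || ymid >= target_y_o2) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
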