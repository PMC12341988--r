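#' Maintenance sensitivity scan
#'
#' Evaluates the growth rate over a grid of GAM or NGAM values and
#' reports piecewise slopes (sensitivities, change in growth rate per
#' mmol ATP) between consecutive feasible grid points.
#'
#' @param model a `metabolic_model`.
#' @param cond a [condition()]; its maintenance spec provides the value
#'   of the parameter not being scanned.
#' @param which `"gam"` or `"ngam"`.
#' @param grid strictly increasing parameter values (mmol ATP/gDW(/h)).
#' @return object of class `scan_result`: list with `parameter`, `grid`,
#'   `mu` (`NA` where infeasible) and `slopes` (data frame `from`, `to`,
#'   `slope`).
#' @export
scan_maintenance <- function(model, cond, which = c("ngam", "gam"), grid) {
  which <- match.arg(which)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (is.null(cond$maintenance)) cond$maintenance <- maintenance_spec()
  mu <- vapply(grid, function(val) {
    ms <- cond$maintenance
    if (which == "gam") ms$gam <- val else ms$ngam <- val
    cond$maintenance <- ms
    sol <- solve_fba(model, cond)
    if (sol$status == "optimal") sol$objective_value else NA_real_
  }, numeric(1))
  .scan_result(which, grid, mu)
}

.scan_result <- function(parameter, grid, mu) {
  ok <- which(!is.na(mu))
  pairs <- ok[which(diff(ok) == 1)]
  slopes <- data.frame(from = grid[pairs], to = grid[pairs + 1],
                       slope = (mu[pairs + 1] - mu[pairs]) /
                               (grid[pairs + 1] - grid[pairs]))
  structure(list(parameter = parameter, grid = grid, mu = mu, slopes = slopes),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> parameter: ", x$parameter, " (", length(x$grid),
      " points, ", sum(is.na(x$mu)), " infeasible)\n", sep = "")
  invisible(x)
}

#' Formaldehyde flux-split scan
#'
#' Scans the fraction of total formaldehyde oxidation routed through the
#' direct cytochrome-coupled dehydrogenase (rather than the THF-dependent
#' pathway), rebuilding the ratio constraint at every grid point. Because
#' the direct route bypasses NAD(P)H and ATP formation, the growth rate
#' is expected to fall as the fraction rises.
#'
#' @param model a `metabolic_model`.
#' @param cond a methane [condition()].
#' @param alpha_grid fractions in `[0, 1]`, strictly increasing.
#' @param focal focal reaction id (default `"FALDHpp"`).
#' @return a `scan_result` (parameter `"faldh_fraction"`).
#' @export
scan_formaldehyde_split <- function(model, cond, alpha_grid,
                                    focal = "FALDHpp") {
  denom <- formaldehyde_consumers(model)
  if (!length(denom)) stop("no formaldehyde-consuming reactions found in model")
  keep <- Filter(function(rc) rc$focal != focal, cond$ratio_constraints)
  mu <- vapply(alpha_grid, function(a) {
    cond$ratio_constraints <- c(keep, list(ratio_constraint(focal, denom, a)))
    sol <- solve_fba(model, cond)
    if (sol$status == "optimal") sol$objective_value else NA_real_
  }, numeric(1))
  .scan_result("faldh_fraction", alpha_grid, mu)
}

#' H2 phase plane
#'
#' Two-dimensional scan over the total H2 uptake rate and the fraction
#' `f` of H2 oxidized by the periplasmic (quinone-coupled) hydrogenase,
#' with complex I reversible. For every feasible cell the growth rate,
#' the complex I flux (positive = NADH-oxidizing, negative = reverse
#' electron flow) and the ATP synthase flux are recorded from
#' parsimonious solutions.
#'
#' @param model a `metabolic_model`.
#' @param h2_grid H2 uptake rates (mmol/gDW/h).
#' @param f_grid periplasmic fractions in `[0, 1]`.
#' @param complex_i,atp_synthase reaction ids to track.
#' @param maintenance a [maintenance_spec()].
#' @return object of class `phase_plane`: list of matrices `mu`,
#'   `complex_i`, `atp_synthase` (rows = `h2_grid`, columns = `f_grid`;
#'   `NA` marks infeasible cells) plus the grids.
#' @export
phase_plane_h2 <- function(model, h2_grid, f_grid,
                           complex_i = "NADH16pp", atp_synthase = "ATPS4rpp",
                           maintenance = maintenance_spec()) {
  shape <- list(length(h2_grid), length(f_grid))
  mu <- ci <- atps <- matrix(NA_real_, shape[[1]], shape[[2]],
                             dimnames = list(h2_grid, f_grid))
  for (i in seq_along(h2_grid)) {
    for (j in seq_along(f_grid)) {
      cond <- build_condition("h2_co2", model = model, h2_uptake = h2_grid[i],
                              hyd_fraction = f_grid[j], maintenance = maintenance)
      sol <- solve_fba(model, cond, solver_settings(parsimonious = TRUE))
      if (sol$status == "optimal") {
        mu[i, j] <- sol$objective_value
        ci[i, j] <- sol$fluxes[[complex_i]]
        atps[i, j] <- sol$fluxes[[atp_synthase]]
      }
    }
  }
  structure(list(h2_grid = h2_grid, f_grid = f_grid, mu = mu,
                 complex_i = ci, atp_synthase = atps),
            class = "phase_plane")
}

#' Fraction at which complex I reverses
#'
#' Bisects the periplasmic H2 fraction `f` for the zero crossing of the
#' complex I flux at a fixed total H2 uptake. Monotonicity of the flux
#' in `f` is checked on a coarse grid first.
#'
#' @param model a `metabolic_model`.
#' @param h2_uptake total H2 uptake (mmol/gDW/h).
#' @param resolution bisection resolution on `f` (default 1e-3).
#' @param complex_i reaction id of complex I.
#' @param maintenance a [maintenance_spec()].
#' @return list with `switch` (the crossing fraction, or `NA` when the
#'   flux does not change sign on `[0, 1]`) and `flux_at` (function-free
#'   record of the coarse-grid fluxes).
#' @export
find_switch_fraction <- function(model, h2_uptake, resolution = 1e-3,
                                 complex_i = "NADH16pp",
                                 maintenance = maintenance_spec()) {
  flux_at <- function(f) {
    cond <- build_condition("h2_co2", model = model, h2_uptake = h2_uptake,
                            hyd_fraction = f, maintenance = maintenance)
    sol <- solve_fba(model, cond, solver_settings(parsimonious = TRUE))
    if (sol$status != "optimal") return(NA_real_)
    sol$fluxes[[complex_i]]
  }
  coarse_f <- seq(0, 1, length.out = 11)
  coarse <- vapply(coarse_f, flux_at, numeric(1))
  ok <- !is.na(coarse)
  if (any(diff(coarse[ok]) > 1e-6)) {
    warning("complex I flux is not non-increasing in f on the coarse grid")
  }
  sgn <- sign(coarse[ok])
  if (all(sgn >= 0) || all(sgn <= 0)) {
    return(list(switch = NA_real_,
                flux_at = data.frame(f = coarse_f, flux = coarse)))
  }
  lo <- max(coarse_f[ok][sgn > 0]); hi <- min(coarse_f[ok][sgn < 0])
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    fm <- flux_at(mid)
    if (is.na(fm) || fm < 0) hi <- mid else lo <- mid
  }
  list(switch = (lo + hi) / 2,
       flux_at = data.frame(f = coarse_f, flux = coarse))
}

#' Minimum H2 uptake supporting growth
#'
#' Bisects the smallest total H2 uptake with feasible positive growth
#' (growth rate above 1e-6/h) at a fixed periplasmic fraction `f`. The
#' default `f = 1` probes the pure reverse-electron-flow regime, where
#' all H2 electrons enter at the quinone level and NADH must be made by
#' running complex I backwards.
#'
#' @param model a `metabolic_model`.
#' @param f periplasmic H2 fraction (default 1).
#' @param upper upper bracket on the uptake (mmol/gDW/h).
#' @param resolution bisection resolution (default 1e-3).
#' @param maintenance a [maintenance_spec()].
#' @return the threshold uptake (mmol/gDW/h).
#' @export
find_min_h2_uptake <- function(model, f = 1, upper = 30, resolution = 1e-3,
                               maintenance = maintenance_spec()) {
  grows <- function(h2) {
    cond <- build_condition("h2_co2", model = model, h2_uptake = h2,
                            hyd_fraction = f, maintenance = maintenance)
    sol <- solve_fba(model, cond)
    sol$status == "optimal" && sol$objective_value > 1e-6
  }
  if (!grows(upper)) stop("no growth at the upper bracket uptake of ", upper)
  lo <- 0; hi <- upper
  if (grows(0)) return(0)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (grows(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Linear response of O2 uptake and CO2 production to CH4 uptake
#'
#' Simulates a range of methane uptake rates, records the parsimonious
#' O2 uptake and CO2 production rates, and fits both against CH4 uptake
#' by ordinary least squares.
#'
#' @param model a `metabolic_model`.
#' @param ch4_grid methane uptake rates (default 20 points over 1-6
#'   mmol/gDW/h).
#' @param maintenance a [maintenance_spec()].
#' @param faldh_fraction formaldehyde split fraction (default 0.2).
#' @return object of class `response_fit`: list with `data` (per-point
#'   rates) and `o2`/`co2` fit summaries (`slope`, `intercept`,
#'   `r_squared`, `log_likelihood`).
#' @export
uptake_response_fit <- function(model, ch4_grid = seq(1, 6, length.out = 20),
                                maintenance = maintenance_spec(),
                                faldh_fraction = 0.2) {
  rows <- lapply(ch4_grid, function(q) {
    cond <- build_condition("ch4", carbon_uptake = q, model = model,
                            faldh_fraction = faldh_fraction,
                            maintenance = maintenance)
    sol <- solve_fba(model, cond, solver_settings(parsimonious = TRUE))
    if (sol$status != "optimal") return(NULL)
    data.frame(ch4 = q, o2 = -sol$fluxes[["EX_o2_e"]],
               co2 = sol$fluxes[["EX_co2_e"]], mu = sol$objective_value)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) < 3) {
    stop("fewer than 3 feasible grid points; cannot fit a response line")
  }
  fit1 <- function(y) {
    m <- stats::lm(y ~ ch4, data = cbind(df, y = y))
    list(slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
         r_squared = summary(m)$r.squared,
         log_likelihood = as.numeric(stats::logLik(m)))
  }
  structure(list(data = df, o2 = fit1(df$o2), co2 = fit1(df$co2)),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("<response_fit> on", nrow(x$data), "points\n")
  for (nm in c("o2", "co2")) {
    f <- x[[nm]]
    cat(sprintf("  %-4s slope=%.4g intercept=%.4g R2=%.3f logLik=%.2f\n",
                toupper(nm), f$slope, f$intercept, f$r_squared, f$log_likelihood))
  }
  invisible(x)
}

#' Substrate growth panel
#'
#' Simulates growth on a panel of substrates at a common carbon uptake
#' rate and reports growth rate, yields and selected (parsimonious)
#' fluxes per substrate. Infeasible substrates are recorded, not fatal.
#'
#' @param model a `metabolic_model`.
#' @param substrates substrate names understood by [build_condition()].
#' @param carbon_uptake carbon uptake (C-mmol/gDW/h, default 3.5).
#' @param track reaction ids whose fluxes to report.
#' @param maintenance a [maintenance_spec()].
#' @param exchanges substrate-role to exchange-id map.
#' @return data frame with one row per substrate: `substrate`, `status`,
#'   `mu`, `q_substrate`, `y_o2`, `y_co2`, `y_x` and one column per
#'   tracked reaction.
#' @export
simulate_substrate_panel <- function(model,
                                     substrates = c("ch4", "propane",
                                                    "isopropanol", "acetone"),
                                     carbon_uptake = 3.5,
                                     track = c("CYTCBB3pp1", "ATPS4rpp"),
                                     maintenance = maintenance_spec(),
                                     exchanges = .default_exchanges) {
  rows <- lapply(substrates, function(s) {
    cond <- build_condition(s, carbon_uptake = carbon_uptake, model = model,
                            maintenance = maintenance, exchanges = exchanges)
    sol <- solve_fba(model, cond, solver_settings(parsimonious = TRUE))
    base <- data.frame(substrate = s, status = sol$status, mu = NA_real_,
                       q_substrate = NA_real_, y_o2 = NA_real_,
                       y_co2 = NA_real_, y_x = NA_real_)
    for (tr in track) base[[tr]] <- NA_real_
    if (sol$status == "optimal") {
      base$mu <- sol$objective_value
      sub_ex <- exchanges[[if (s == "h2_co2") "h2" else s]]
      base$q_substrate <- abs(sol$fluxes[[sub_ex]])
      ys <- tryCatch(
        compute_yields(sol, sub_ex, o2_exchange = exchanges[["o2"]],
                       co2_exchange = exchanges[["co2"]]),
        error = function(e) NULL)            # zero uptake: yields undefined
      if (!is.null(ys)) {
        base$y_o2 <- ys$y_o2; base$y_co2 <- ys$y_co2; base$y_x <- ys$y_x
      }
      for (tr in track) {
        if (tr %in% names(sol$fluxes)) base[[tr]] <- sol$fluxes[[tr]]
      }
    }
    base
  })
  do.call(rbind, rows)
}
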