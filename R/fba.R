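#' Linear flux-split (ratio) constraint
#'
#' Encodes the equality \eqn{v_{focal} = \phi \sum_{r \in D} v_r} used to
#' pin the share of a branch in a total oxidation flux, e.g. the fraction
#' of formaldehyde oxidized directly by the XoxF methanol dehydrogenase
#' or the fraction of H2 oxidized by the periplasmic hydrogenase. The
#' constraint enters the linear program as an extra equality row (never
#' as bound manipulation) so it composes correctly with flux variability
#' analysis and sampling.
#'
#' @param focal focal reaction id.
#' @param denominator character vector of reaction ids whose summed flux
#'   forms the denominator; must contain `focal`.
#' @param fraction dimensionless share in `[0, 1]`.
#' @return an object of class `ratio_constraint`.
#' @export
ratio_constraint <- function(focal, denominator, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1) {
    stop("ratio fraction must be a single number in [0, 1], got ", fraction)
  }
  if (!focal %in% denominator) {
    stop("denominator must include the focal reaction '", focal, "'")
  }
  structure(list(focal = focal, denominator = denominator, fraction = fraction),
            class = "ratio_constraint")
}

#' Solver settings
#' @param tolerance numeric feasibility/pivot tolerance.
#' @param parsimonious logical; if `TRUE`, report fluxes from a second
#'   stage that minimizes total absolute flux at the fixed optimum.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(tolerance = 1e-9, parsimonious = FALSE) {
  stopifnot(tolerance > 0)
  structure(list(tolerance = tolerance, parsimonious = parsimonious),
            class = "solver_settings")
}

## Assemble the LP (equality rows = mass balances + ratio rows) for a
## model with an optional condition applied.
.build_lp <- function(model, condition = NULL) {
  if (!is.null(condition)) model <- apply_condition(model, condition)
  S <- stoich_matrix(model)
  bounds <- flux_bounds(model)
  rcs <- if (!is.null(condition)) condition$ratio_constraints else list()
  extra <- matrix(0, length(rcs), ncol(S), dimnames = list(NULL, colnames(S)))
  if (length(rcs)) {
    for (i in seq_along(rcs)) {
      rc <- rcs[[i]]
      unknown <- setdiff(c(rc$focal, rc$denominator), colnames(S))
      if (length(unknown)) {
        stop("ratio constraint references unknown reaction(s): ",
             paste(unknown, collapse = ", "))
      }
      extra[i, rc$denominator] <- -rc$fraction
      extra[i, rc$focal] <- extra[i, rc$focal] + 1
    }
  }
  obj <- as.numeric(colnames(S) == model$objective_id)
  list(A = rbind(S, extra), b = rep(0, nrow(S) + length(rcs)),
       lb = bounds$lb, ub = bounds$ub, obj = obj,
       reactions = colnames(S), model = model)
}

#' Flux balance analysis
#'
#' Maximizes the objective (biomass) flux subject to the steady-state
#' constraint \eqn{Sv = 0}, flux bounds, and any ratio constraints
#' carried by the condition. With `settings$parsimonious = TRUE` a
#' second LP minimizes \eqn{\sum_r |v_r|} while holding the objective at
#' its optimum (positive/negative flux-split reformulation), giving a
#' deterministic representative among degenerate optima.
#'
#' @param model a `metabolic_model`.
#' @param condition optional [condition()] with uptake bounds, ratio
#'   constraints, reversibility overrides and maintenance settings.
#' @param settings a [solver_settings()].
#' @return object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value`
#'   (growth rate, 1/h, when the objective is biomass) and `fluxes`
#'   (named vector, mmol/gDW/h; empty unless optimal).
#' @export
solve_fba <- function(model, condition = NULL, settings = solver_settings()) {
  lp <- .build_lp(model, condition)
  res <- lp_solve(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE,
                  tol = settings$tolerance)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = stats::setNames(numeric(0), character(0))),
                     class = "flux_solution"))
  }
  fluxes <- stats::setNames(res$x, lp$reactions)
  if (isTRUE(settings$parsimonious)) {
    fluxes <- .pfba_stage(lp, res$objective, settings$tolerance)
  }
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = fluxes),
            class = "flux_solution")
}

## stage-2 parsimonious refinement: v = p - q, minimize sum(p + q)
## subject to A(p - q) = b and the objective pinned at its optimum.
.pfba_stage <- function(lp, opt, tol) {
  n <- length(lp$reactions)
  A2 <- cbind(rbind(lp$A, lp$obj), -rbind(lp$A, lp$obj))
  b2 <- c(lp$b, opt)
  lbp <- pmax(lp$lb, 0); ubp <- pmax(lp$ub, 0)
  lbq <- pmax(-lp$ub, 0); ubq <- pmax(-lp$lb, 0)
  res <- lp_solve(rep(1, 2 * n), A2, b2, c(lbp, lbq), c(ubp, ubq),
                  maximize = FALSE, tol = tol)
  if (res$status != "optimal") {
    stop("parsimonious stage failed with status: ", res$status)
  }
  stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], lp$reactions)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat("   objective: ", format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with an
#' objective value of at least `fraction_of_optimum` times the optimum.
#' Used to diagnose degenerate optima and to bound the sampling
#' polytope.
#'
#' @param model a `metabolic_model`.
#' @param condition optional [condition()].
#' @param fraction_of_optimum number in `[0, 1]`; `0` leaves growth free.
#' @param reactions optional subset of reaction ids.
#' @param settings a [solver_settings()].
#' @return data frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, condition = NULL, fraction_of_optimum = 1,
                             reactions = NULL, settings = solver_settings()) {
  lp <- .build_lp(model, condition)
  A <- lp$A; b <- lp$b; lb <- lp$lb; ub <- lp$ub
  if (fraction_of_optimum > 0) {
    base <- lp_solve(lp$obj, A, b, lb, ub, maximize = TRUE,
                     tol = settings$tolerance)
    if (base$status != "optimal") {
      stop("flux_variability: base problem is ", base$status)
    }
    ## c'v - s = f * opt with slack s >= 0  <=>  c'v >= f * opt
    A <- cbind(rbind(A, lp$obj), c(rep(0, nrow(A)), -1))
    b <- c(b, fraction_of_optimum * base$objective)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  idx <- if (is.null(reactions)) seq_along(lp$reactions) else
    match(reactions, lp$reactions)
  if (anyNA(idx)) stop("unknown reaction(s) in 'reactions'")
  out <- data.frame(reaction = lp$reactions[idx], min = NA_real_, max = NA_real_)
  nv <- ncol(A)
  for (k in seq_along(idx)) {
    cvec <- numeric(nv); cvec[idx[k]] <- 1
    lo <- lp_solve(cvec, A, b, lb, ub, maximize = FALSE, tol = settings$tolerance)
    hi <- lp_solve(cvec, A, b, lb, ub, maximize = TRUE, tol = settings$tolerance)
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("flux_variability: infeasible subproblem for ", lp$reactions[idx[k]])
    }
    out$min[k] <- if (lo$status == "unbounded") -Inf else lo$objective
    out$max[k] <- if (hi$status == "unbounded") Inf else hi$objective
  }
  out
}
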