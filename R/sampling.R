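#' Uniformly sample the steady-state flux polytope
#'
#' Artificially-centered coordinate hit-and-run over
#' \eqn{\{v : Sv = 0,\ lb \le v \le ub\}} plus any ratio-constraint rows
#' of the condition. Warmup points are the flux variability vertices
#' (one minimization and one maximization per reaction); chain
#' directions are differences between a random warmup point and the
#' running center, projected onto the null space of the equality rows
#' (with bound-pinned coordinates removed). Growth is left free unless
#' `min_growth_fraction` is set.
#'
#' @param model a `metabolic_model`.
#' @param cond a [condition()].
#' @param n_samples number of samples to keep (default 10000).
#' @param seed integer seed; every run with the same seed yields the
#'   identical sample matrix.
#' @param thinning keep every `thinning`-th chain point (default 100).
#' @param warmup_steps chain steps discarded before recording (default
#'   10 x number of reactions).
#' @param min_growth_fraction if nonzero, constrain the objective to at
#'   least this fraction of its optimum during sampling.
#' @return object of class `flux_sample_set`: list with `condition`
#'   (name), `reactions`, `samples` (n_samples x n_reactions matrix),
#'   `seed`, `n_samples`, `thinning`, `warmup_steps`.
#' @export
sample_fluxes <- function(model, cond, n_samples = 10000, seed = 1L,
                          thinning = 100, warmup_steps = NULL,
                          min_growth_fraction = 0) {
  lp <- .build_lp(model, cond)
  A <- lp$A; lb <- lp$lb; ub <- lp$ub
  if (min_growth_fraction > 0) {
    base <- lp_solve(lp$obj, A, lp$b, lb, ub, maximize = TRUE)
    if (base$status != "optimal") stop("condition is ", base$status)
    smax <- (1 - min_growth_fraction) * abs(base$objective) + 1
    A <- cbind(rbind(A, lp$obj), c(rep(0, nrow(A)), -1))
    lb <- c(lb, 0); ub <- c(ub, smax)
  }
  n <- ncol(A)
  ## warmup vertices by per-coordinate optimization (FVA corners)
  pts <- matrix(NA_real_, 2 * n, n)
  b <- rep(0, nrow(A))
  if (min_growth_fraction > 0) {
    b[length(b)] <- min_growth_fraction *
      lp_solve(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)$objective
  }
  for (i in seq_len(n)) {
    cv <- numeric(n); cv[i] <- 1
    for (dir in c(-1, 1)) {
      r <- lp_solve(dir * cv, A, b, lb, ub, maximize = TRUE)
      if (r$status == "unbounded") {
        stop("polytope unbounded in direction of variable ", i,
             " (", lp$reactions[min(i, length(lp$reactions))], ")")
      }
      if (r$status != "optimal") stop("sampling condition is ", r$status)
      pts[2 * i - 2 + (dir + 3) / 2, ] <- r$x
    }
  }
  ## null-space projector; bound-pinned coordinates count as equalities
  pinned <- which(ub - lb < 1e-9)
  Adir <- A
  if (length(pinned)) {
    E <- matrix(0, length(pinned), n)
    E[cbind(seq_along(pinned), pinned)] <- 1
    Adir <- rbind(A, E)
  }
  P <- .nullspace_projector(Adir)
  x0 <- colMeans(pts)
  if (is.null(warmup_steps)) warmup_steps <- 10L * n
  set.seed(seed)
  samples <- achr_core(pts, x0, P, lb, ub, as.integer(n_samples),
                       as.integer(thinning), as.integer(warmup_steps), 1e-10)
  keep <- seq_along(lp$reactions)
  samples <- samples[, keep, drop = FALSE]
  colnames(samples) <- lp$reactions
  structure(list(condition = cond$name, reactions = lp$reactions,
                 samples = samples, seed = seed, n_samples = n_samples,
                 thinning = thinning, warmup_steps = warmup_steps),
            class = "flux_sample_set")
}

.nullspace_projector <- function(A) {
  n <- ncol(A)
  if (nrow(A) == 0) return(diag(n))
  sv <- svd(A, nu = 0, nv = n)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  r <- sum(pos)
  if (r >= n) return(matrix(0, n, n))
  N <- sv$v[, (r + 1):n, drop = FALSE]
  N %*% t(N)
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set> condition: ", x$condition, "\n", sep = "")
  cat("  ", nrow(x$samples), " samples x ", length(x$reactions),
      " reactions  (seed ", x$seed, ", thinning ", x$thinning,
      ", warmup ", x$warmup_steps, ")\n", sep = "")
  invisible(x)
}

#' Validate a flux sample set against its model
#'
#' Checks every sampled flux vector for steady state (max |S v| per
#' row), bound violations, and optionally containment of the empirical
#' per-reaction ranges in flux variability ranges.
#'
#' @param sample_set a `flux_sample_set`.
#' @param model the `metabolic_model` it was drawn from.
#' @param cond the [condition()] it was drawn under.
#' @param fva optional data frame from [flux_variability()] for the
#'   range-containment check.
#' @param tol violation tolerance (default 1e-6).
#' @return list with `max_residual` (per row), `n_bound_violations`,
#'   `bad_rows` (indices with any violation), and `ranges_ok`
#'   (`NA` unless `fva` supplied).
#' @export
check_sample_validity <- function(sample_set, model, cond, fva = NULL,
                                  tol = 1e-6) {
  lp <- .build_lp(model, cond)
  X <- sample_set$samples
  if (!identical(colnames(X), lp$reactions)) {
    stop("sample set and model/condition reaction sets differ")
  }
  resid <- abs(X %*% t(lp$A))
  max_residual <- apply(resid, 1, max)
  viol <- sweep(X, 2, lp$lb, `-`) < -tol | sweep(X, 2, lp$ub, `-`) > tol
  n_bound_violations <- sum(viol)
  bad <- which(max_residual > tol | rowSums(viol) > 0)
  ranges_ok <- NA
  if (!is.null(fva)) {
    emp_min <- apply(X, 2, min); emp_max <- apply(X, 2, max)
    m <- match(lp$reactions, fva$reaction)
    ranges_ok <- all(emp_min >= fva$min[m] - tol) &&
      all(emp_max <= fva$max[m] + tol)
  }
  list(max_residual = max_residual, n_bound_violations = n_bound_violations,
       bad_rows = bad, ranges_ok = ranges_ok)
}
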