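#' Solve a bounded linear program
#'
#' Dense two-phase revised simplex for problems of the form
#' optimize \eqn{c'x} subject to \eqn{Ax = b} and \eqn{l \le x \le u}.
#' This is the numerical core behind every flux-balance solve in the
#' package; problems are small (tens to a few hundred variables) so a
#' dense implementation with Bland's anti-cycling rule is both fast
#' enough and numerically transparent. Redundant equality rows are
#' tolerated: artificial variables simply remain basic at zero.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A dense constraint matrix (`m` x `n`).
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; infinities are allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (primal solution, length `n`, `NA` unless
#'   optimal) and `objective` (value of `obj' x`).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }

  ## nonbasic start: the finite bound closest to zero, or 0 for free variables
  free <- !is.finite(lb) & !is.finite(ub)
  use_lb <- is.finite(lb) & (!is.finite(ub) | abs(lb) <= abs(ub))
  start_val <- ifelse(free, 0, ifelse(use_lb, lb, ub))
  ## status codes: 0 basic, 1 at lb, 2 at ub, 3 free at zero
  stat <- integer(n + m)
  stat[seq_len(n)] <- ifelse(free, 3L, ifelse(use_lb, 1L, 2L))
  x <- numeric(n + m)
  x[seq_len(n)] <- start_val

  r <- as.vector(b - A %*% x[seq_len(n)])
  s <- ifelse(r < 0, -1, 1)
  Aall <- cbind(A, diag(s, m))
  lbar <- c(lb, rep(0, m))
  ubar <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  stat[basis] <- 0L
  x[basis] <- abs(r)

  iter_used <- 0L
  run_phase <- function(cost, lbar, ubar) {
    repeat {
      iter_used <<- iter_used + 1L
      if (iter_used > max_iter) stop("lp_solve: iteration limit reached")
      B <- Aall[, basis, drop = FALSE]
      Binv <- solve(B)
      xb <- Binv %*% (b - Aall[, -basis, drop = FALSE] %*% x[-basis])
      x[basis] <<- as.vector(xb)
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost - as.vector(crossprod(Aall, y))   # reduced costs (min sense)
      enter <- 0L; sigma <- 0
      for (j in seq_len(n + m)) {               # Bland: smallest eligible index
        if (stat[j] == 0L) next
        if (stat[j] == 1L && d[j] < -tol) { enter <- j; sigma <- 1; break }
        if (stat[j] == 2L && d[j] >  tol) { enter <- j; sigma <- -1; break }
        if (stat[j] == 3L && abs(d[j]) > tol) { enter <- j; sigma <- -sign(d[j]); break }
      }
      if (enter == 0L) return("optimal")
      w <- as.vector(Binv %*% Aall[, enter])
      ## ratio test over basic variables plus the entering variable's own span
      wb <- sigma * w
      ratio <- rep(Inf, m)
      hit_lb <- wb > tol & is.finite(lbar[basis])
      hit_ub <- wb < -tol & is.finite(ubar[basis])
      ratio[hit_lb] <- (x[basis][hit_lb] - lbar[basis][hit_lb]) / wb[hit_lb]
      ratio[hit_ub] <- (ubar[basis][hit_ub] - x[basis][hit_ub]) / (-wb[hit_ub])
      t_own <- if (is.finite(lbar[enter]) && is.finite(ubar[enter]))
        ubar[enter] - lbar[enter] else Inf
      t_max <- min(t_own, ratio)
      if (!is.finite(t_max)) return("unbounded")
      t_max <- max(t_max, 0)
      leave <- 0L
      if (min(ratio) <= t_own + tol && any(is.finite(ratio))) {
        near <- which(ratio <= t_max + tol)
        if (length(near)) {
          leave <- near[which.min(basis[near])]  # Bland tie-break on index
          leave_stat <- if (hit_lb[leave]) 1L else 2L
          leave_bound <- if (leave_stat == 1L) lbar[basis[leave]] else ubar[basis[leave]]
        }
      }
      ## apply the step
      x[basis] <<- x[basis] - sigma * t_max * w
      x[enter] <<- x[enter] + sigma * t_max
      if (leave == 0L) {                         # bound flip, basis unchanged
        stat[enter] <<- if (stat[enter] == 1L) 2L else 1L
        x[enter] <<- if (stat[enter] == 1L) lbar[enter] else ubar[enter]
      } else {
        out <- basis[leave]
        stat[out] <<- leave_stat
        x[out] <<- leave_bound
        basis[leave] <<- enter
        stat[enter] <<- 0L
      }
    }
  }

  ## phase 1: drive artificial variables to zero
  cost1 <- c(rep(0, n), rep(1, m))
  st <- run_phase(cost1, lbar, ubar)
  if (st != "optimal" || sum(x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }

  ## phase 2: pin artificials at zero, optimize the true objective
  ubar[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- pmax(pmin(x[n + seq_len(m)], 0), 0)
  cost2 <- c(if (maximize) -obj else obj, rep(0, m))
  st <- run_phase(cost2, lbar, ubar)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  xr <- x[seq_len(n)]
  list(status = "optimal", x = xr, objective = sum(obj * xr))
}
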