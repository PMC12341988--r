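test_that("standard conditions encode the carbon-normalized uptakes", {
  m <- mini_model()
  cond <- build_condition("propane", carbon_uptake = 3.5, model = m)
  expect_equal(cond$uptake_bounds[["EX_ppa_e"]], 3.5 / 3, tolerance = 1e-9)
  cond <- build_condition("ch4", carbon_uptake = 3.5, model = m)
  expect_equal(cond$uptake_bounds[["EX_ch4_e"]], 3.5)
  expect_length(cond$ratio_constraints, 1)
  expect_equal(cond$ratio_constraints[[1]]$fraction, 0.2)
  expect_setequal(cond$ratio_constraints[[1]]$denominator,
                  c("FALDHpp", "FALDTHF"))
  cond <- build_condition("acetone", carbon_uptake = 0, model = m)
  expect_equal(cond$uptake_bounds[["EX_actn_e"]], 0)
  auto <- build_condition("h2_co2", model = m)
  expect_equal(auto$uptake_bounds[["EX_h2_e"]], 13.2)
  expect_equal(auto$reversible_overrides[["NADH16pp"]], c(-1000, 1000))
  expect_equal(auto$ratio_constraints[[1]]$fraction, 0.76)
  expect_error(build_condition("glucose"), "arg")
})

test_that("condition YAML files round trip", {
  m <- mini_model()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("substrate: ch4", "carbon_uptake: 3.5", "ngam: 3.5",
               "gam: 10.86"), f)
  cond <- read_condition_yaml(f, model = m)
  expect_equal(cond$uptake_bounds[["EX_ch4_e"]], 3.5)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_condition_yaml(cond, f2)
  cond2 <- read_condition_yaml(f2, model = m)
  expect_equal(cond2$uptake_bounds, cond$uptake_bounds)
  expect_equal(cond2$ratio_constraints[[1]]$fraction,
               cond$ratio_constraints[[1]]$fraction)
})

test_that("growth is non-increasing in NGAM, with an infeasible tail", {
  m <- mini_model()
  res <- scan_maintenance(m, mini_condition("ch4"), "ngam", seq(0, 20, by = 1))
  mu <- res$mu
  ok <- !is.na(mu)
  expect_true(all(diff(mu[ok]) <= 1e-9))
  expect_true(any(!ok))                       # infeasible above some NGAM
  expect_true(all(which(!ok) > max(which(ok)[1]))) # tail, not interior holes
  ## spot-check two grid points against direct LP solves
  for (k in c(3, 9)) {
    cond <- mini_condition("ch4")
    cond$maintenance <- maintenance_spec(gam = 10.86, ngam = res$grid[k])
    lp <- redoxflux:::.build_lp(m, cond)
    direct <- redoxflux:::lp_solve(lp$obj, lp$A, lp$b, lp$lb, lp$ub)
    expect_equal(mu[k], direct$objective, tolerance = 1e-8)
  }
  expect_equal(nrow(res$slopes), sum(ok) - 1)
})

test_that("growth is insensitive to GAM at low values", {
  m <- mini_model()
  res <- scan_maintenance(m, mini_condition("ch4"), "gam", seq(0, 30, by = 5))
  expect_true(all(diff(res$mu) <= 1e-9))
})

test_that("growth falls monotonically with the formaldehyde split", {
  m <- mini_model()
  res <- scan_formaldehyde_split(m, mini_condition("ch4"),
                                 seq(0, 1, length.out = 21))
  ok <- !is.na(res$mu)
  expect_true(all(diff(res$mu[ok]) <= 1e-9))
  ## alpha = 0 equals the unconstrained THF-only optimum
  cond0 <- mini_condition("ch4")
  cond0$ratio_constraints <- list()
  m0 <- apply_condition(m, cond0)
  m0 <- set_bounds(m0, "FALDHpp", ub = 0)
  expect_equal(res$mu[1], solve_fba(m0)$objective_value, tolerance = 1e-8)
})

test_that("H2 phase plane exhibits the reverse-electron-flow trade-off", {
  m <- mini_model()
  pp <- phase_plane_h2(m, h2_grid = c(8, 13.2), f_grid = seq(0, 1, 0.25))
  ## growth non-increasing in f at fixed uptake
  for (i in 1:2) {
    row <- pp$mu[i, ]
    ok <- !is.na(row)
    expect_true(all(diff(row[ok]) <= 1e-8))
  }
  ## complex I forward at f = 0, ATP synthase lower at f = 1 than f = 0
  expect_gte(pp$complex_i[2, 1], 0)
  expect_lt(pp$atp_synthase[2, 5], pp$atp_synthase[2, 1])
})

test_that("switch-fraction bisection matches a fine grid scan", {
  m <- mini_model()
  sw <- find_switch_fraction(m, 13.2)
  expect_false(is.na(sw$switch))
  expect_gt(sw$switch, 0); expect_lt(sw$switch, 1)
  ## grid oracle at 2e-3 resolution around the crossing
  fgrid <- seq(max(0, sw$switch - 0.02), min(1, sw$switch + 0.02), by = 0.002)
  flux <- vapply(fgrid, function(f) {
    cond <- build_condition("h2_co2", model = m, hyd_fraction = f)
    solve_fba(m, cond, solver_settings(parsimonious = TRUE))$fluxes[["NADH16pp"]]
  }, numeric(1))
  crossing <- fgrid[which.max(flux < 0)]
  expect_lt(abs(sw$switch - crossing), 5e-3)
})

test_that("a variant without the cytosolic hydrogenase has no switch", {
  m <- mini_model()
  m$reactions$NAD_H2 <- NULL
  m$reactions$H2tcp <- NULL
  m$metabolites <- m$metabolites[m$metabolites$id != "h2_c", ]
  sw <- find_switch_fraction(m, 13.2)
  expect_true(is.na(sw$switch))
  feasible <- sw$flux_at$flux[!is.na(sw$flux_at$flux)]
  expect_true(all(feasible <= 1e-8))          # complex I always in reverse
})

test_that("minimum-uptake bisection matches a grid scan and NGAM limit", {
  m <- mini_model()
  thr <- find_min_h2_uptake(m, f = 1)
  expect_gt(thr, 0)
  grows <- function(h2) {
    cond <- build_condition("h2_co2", model = m, h2_uptake = h2,
                            hyd_fraction = 1)
    sol <- solve_fba(m, cond)
    sol$status == "optimal" && sol$objective_value > 1e-6
  }
  grid <- seq(max(0, thr - 0.02), thr + 0.02, by = 0.002)
  oracle <- grid[which.max(vapply(grid, grows, logical(1)))]
  expect_equal(thr, oracle, tolerance = 3e-3)
  ## without maintenance any positive uptake supports growth
  thr0 <- find_min_h2_uptake(m, f = 1,
                             maintenance = maintenance_spec(gam = 10.86,
                                                            ngam = 0))
  expect_lt(thr0, 2e-3)
})

test_that("uptake-response OLS equals the closed-form normal equations", {
  m <- mini_model()
  rf <- uptake_response_fit(m, ch4_grid = seq(1, 6, length.out = 8))
  x <- rf$data$ch4
  for (nm in c("o2", "co2")) {
    y <- rf$data[[nm]]
    slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(rf[[nm]]$slope, slope, tolerance = 1e-10)
    expect_equal(rf[[nm]]$intercept, intercept, tolerance = 1e-10)
    r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
    expect_equal(rf[[nm]]$r_squared, r2, tolerance = 1e-10)
  }
  ## the model's respiratory response is essentially linear in CH4 uptake
  expect_gt(rf$o2$r_squared, 0.99)
  expect_error(uptake_response_fit(m, ch4_grid = c(1, 2)), "3 feasible")
})

test_that("the substrate panel reproduces the heterotrophic ordering", {
  m <- mini_model()
  pan <- simulate_substrate_panel(m)
  expect_identical(pan$status, rep("optimal", 4))
  mu <- stats::setNames(pan$mu, pan$substrate)
  expect_gt(mu[["isopropanol"]], mu[["acetone"]])
  expect_gt(mu[["isopropanol"]], mu[["propane"]])
  ## cytochrome oxidase carries more flux on isopropanol
  cy <- stats::setNames(pan$CYTCBB3pp1, pan$substrate)
  expect_gt(cy[["isopropanol"]], cy[["acetone"]])
  expect_gt(cy[["isopropanol"]], cy[["propane"]])
  ## all-zero uptake with zero maintenance: every substrate idles at mu = 0
  pan0 <- simulate_substrate_panel(
    m, carbon_uptake = 0,
    maintenance = maintenance_spec(gam = 10.86, ngam = 0))
  expect_true(all(pan0$status == "optimal"))
  expect_true(all(abs(pan0$mu) < 1e-9))
})
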