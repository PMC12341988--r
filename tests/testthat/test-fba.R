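test_that("FBA optimum matches the brute-force LP oracle on random models", {
  agree <- 0
  for (seed in 21:35) {
    inst <- random_tiny_lp(seed)
    want <- brute_force_lp(inst$obj, inst$A, inst$b, inst$lb, inst$ub)
    got <- redoxflux:::lp_solve(inst$obj, inst$A, inst$b, inst$lb, inst$ub)
    if (want$feasible) {
      expect_equal(got$objective, want$objective, tolerance = 1e-6)
      agree <- agree + 1
    }
  }
  expect_gte(agree, 10)
})

test_that("closed exchanges with zero maintenance give zero growth", {
  m <- mini_model()
  cond <- condition("closed", uptake_bounds = numeric(0),
                    maintenance = maintenance_spec(gam = 10.86, ngam = 0))
  sol <- solve_fba(m, cond)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("steady state holds at every reported optimum", {
  m <- mini_model()
  for (substrate in c("ch4", "isopropanol")) {
    sol <- solve_fba(m, mini_condition(substrate),
                     solver_settings(parsimonious = TRUE))
    S <- stoich_matrix(apply_condition(m, mini_condition(substrate)))
    expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
  }
})

test_that("ratio constraints pin the flux split exactly", {
  m <- toy_split_model(source_flux = 10)
  rc <- ratio_constraint("F", c("F", "T"), 0.2)
  cond <- condition("split", ratio_constraints = list(rc),
                    close_other_uptakes = FALSE)
  sol <- solve_fba(m, cond, solver_settings(parsimonious = TRUE))
  expect_equal(unname(sol$fluxes[["F"]]), 2, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["T"]]), 8, tolerance = 1e-8)

  ## fraction 0: focal branch carries nothing
  cond0 <- condition("s0", ratio_constraints =
                       list(ratio_constraint("F", c("F", "T"), 0)),
                     close_other_uptakes = FALSE)
  expect_equal(unname(solve_fba(m, cond0,
    solver_settings(parsimonious = TRUE))$fluxes[["F"]]), 0, tolerance = 1e-9)

  ## fraction 1: the other branch is forced to zero
  cond1 <- condition("s1", ratio_constraints =
                       list(ratio_constraint("F", c("F", "T"), 1)),
                     close_other_uptakes = FALSE)
  expect_equal(unname(solve_fba(m, cond1,
    solver_settings(parsimonious = TRUE))$fluxes[["T"]]), 0, tolerance = 1e-9)
})

test_that("ratio constraints validate their inputs", {
  expect_error(ratio_constraint("F", c("F", "T"), 1.2), "\\[0, 1\\]")
  expect_error(ratio_constraint("F", c("T"), 0.5), "focal")
  m <- toy_split_model()
  cond <- condition("bad", ratio_constraints =
                      list(ratio_constraint("NOPE", c("NOPE", "T"), 0.5)),
                    close_other_uptakes = FALSE)
  expect_error(solve_fba(m, cond), "unknown reaction")
})

test_that("adding constraints never increases the optimum", {
  m <- mini_model()
  free <- build_condition("ch4", model = m, faldh_fraction = NA)
  base <- solve_fba(m, free)$objective_value
  for (frac in c(0.1, 0.5, 0.9)) {
    cond <- free
    cond$ratio_constraints <- list(
      ratio_constraint("FALDHpp", formaldehyde_consumers(m), frac))
    mu <- solve_fba(m, cond)$objective_value
    expect_lte(mu, base + 1e-9)
  }
  tight <- free
  tight$reversible_overrides[["ATPS4rpp"]] <- c(0, 5)
  expect_lte(solve_fba(m, tight)$objective_value, base + 1e-9)
})

test_that("parsimonious refinement preserves the optimum and reduces |v|", {
  m <- mini_model()
  cond <- mini_condition("ch4")
  plain <- solve_fba(m, cond)
  pars <- solve_fba(m, cond, solver_settings(parsimonious = TRUE))
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-9)
  expect_equal(unname(pars$fluxes[["BIOMASS"]]), plain$objective_value,
               tolerance = 1e-6)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
})

test_that("flux variability brackets behave on structured toys", {
  chain <- toy_chain_model(input_ub = 1)
  chain$reactions$EX_a$lb <- 1          # fix the input
  fva <- flux_variability(chain, fraction_of_optimum = 0)
  expect_equal(fva$min, rep(1, 3), tolerance = 1e-8)
  expect_equal(fva$max, rep(1, 3), tolerance = 1e-8)

  split <- toy_split_model(source_flux = 10)
  fva <- flux_variability(split, fraction_of_optimum = 1)
  f <- fva[fva$reaction %in% c("F", "T"), ]
  expect_equal(f$min, c(0, 0), tolerance = 1e-8)
  expect_equal(f$max, c(10, 10), tolerance = 1e-8)
})

test_that("flux variability matches per-reaction LP oracles on the mini-model", {
  m <- mini_model()
  cond <- mini_condition("ch4")
  ids <- c("PMMOipp", "FALDHpp", "CBB", "ATPS4rpp")
  fva <- flux_variability(m, cond, fraction_of_optimum = 1, reactions = ids)
  lp <- redoxflux:::.build_lp(m, cond)
  opt <- redoxflux:::lp_solve(lp$obj, lp$A, lp$b, lp$lb, lp$ub)$objective
  A <- rbind(lp$A, lp$obj); b <- c(lp$b, opt)
  for (k in seq_along(ids)) {
    cv <- as.numeric(lp$reactions == ids[k])
    lo <- redoxflux:::lp_solve(cv, A, b, lp$lb, lp$ub, maximize = FALSE)
    hi <- redoxflux:::lp_solve(cv, A, b, lp$lb, lp$ub, maximize = TRUE)
    expect_equal(fva$min[k], lo$objective, tolerance = 1e-6)
    expect_equal(fva$max[k], hi$objective, tolerance = 1e-6)
  }
})
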