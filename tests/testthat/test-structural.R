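test_that("closed form matches the ODE oracle at the typical parameters", {
  p <- typical()
  reg <- dose_regimen(0, 10)
  # 138.236011 frozen from the depot/central ODE integration (lsoda,
  # rtol 1e-10) at t = 0.9749 h
  expect_equal(conc_single_dose(p, 10, 0.9749), 138.236011, tolerance = 1e-6)
  grid <- c(0.5, 0.9749, 2, 4, 8, 12, 24)
  closed <- conc_profile(p, reg, grid)
  ode <- ode_oracle(p, reg, grid)
  expect_lt(max(abs(closed - ode) / closed), 1e-6)
})

test_that("concentration is zero before the lag time and continuous at it", {
  p <- typical()
  expect_identical(conc_single_dose(p, 10, 0.3), 0)
  expect_identical(conc_single_dose(p, 10, p$tlag), 0)
  expect_lt(conc_single_dose(p, 10, p$tlag + 1e-9), 1e-3)
})

test_that("ka = ke degenerate case uses a continuous limit form", {
  ke <- 16.9 / 61.7
  p_eq <- structural_params(ka = ke, v = 61.7, cl = 16.9, tlag = 0.394)
  t <- c(0.5, 1, 3, 8)
  c_eq <- conc_single_dose(p_eq, 10, t)
  expect_true(all(is.finite(c_eq) & c_eq >= 0))
  for (f in c(1 - 1e-6, 1 + 1e-6)) {
    p_near <- structural_params(ka = ke * f, v = 61.7, cl = 16.9, tlag = 0.394)
    expect_equal(conc_single_dose(p_near, 10, t), c_eq, tolerance = 1e-4)
  }
})

test_that("superposition is linear in dose and over events", {
  p <- typical()
  grid <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12)
  one <- conc_profile(p, dose_regimen(0, 10), grid)
  expect_equal(one, conc_single_dose(p, 10, grid))
  expect_equal(conc_profile(p, dose_regimen(c(0, 0), c(10, 10)), grid), 2 * one)
  expect_equal(conc_profile(p, dose_regimen(0, 20), grid), 2 * one)
  # 280 mg peak = 28 x the 10 mg peak by dose proportionality
  expect_equal(typical_tmax_cmax(p, 280)$cmax, 3870.6083, tolerance = 1e-6)
  # shifted second dose adds the shifted single-dose curve
  two <- conc_profile(p, dose_regimen(c(0, 6), c(10, 10)), grid)
  shift <- ifelse(grid >= 6, conc_single_dose(p, 10, pmax(grid - 6, 0)), 0)
  expect_equal(two, one + shift)
})

test_that("closed-form peak agrees with a dense-grid argmax", {
  p <- typical()
  pk <- typical_tmax_cmax(p, 10)
  expect_equal(pk$tmax, 0.9748, tolerance = 1e-3)   # 1e-4 h grid oracle
  expect_equal(pk$cmax, 138.236011, tolerance = 1e-6)
  # tlag = 0, ka = 2 ke has the closed-form peak time ln(2)/ke
  ke <- 0.5
  p2 <- structural_params(ka = 2 * ke, v = 10, cl = 5, tlag = 0)
  expect_equal(typical_tmax_cmax(p2, 10)$tmax, log(2) / ke, tolerance = 1e-12)
  # doubling dose doubles cmax, leaves tmax unchanged
  pk2 <- typical_tmax_cmax(p, 20)
  expect_equal(pk2$tmax, pk$tmax)
  expect_equal(pk2$cmax, 2 * pk$cmax)
  # cmax dominates every grid value
  expect_gte(pk$cmax, max(conc_single_dose(p, 10, seq(0, 24, 0.01))))
})

test_that("closed form and ODE oracle agree over random parameter draws", {
  draws <- random_params(60, seed = 101)
  grid <- c(0.5, 1, 2, 4, 8, 16, 24)
  for (p in draws) {
    reg <- dose_regimen(0, 50)
    closed <- conc_profile(p, reg, grid)
    ode <- ode_oracle(p, reg, grid)
    # relative agreement down to 8 decades below the peak; further down the
    # integrator's absolute tolerance dominates and the comparison is moot
    expect_lt(max(abs(closed - ode) / pmax(closed, 1e-8 * max(closed))), 1e-6)
  }
})

test_that("analytic AUC identity: integral of C equals 1000 dose / CL", {
  p <- typical()
  f <- function(t) conc_single_dose(p, 10, t)
  auc <- stats::integrate(Vectorize(f), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(auc, 1000 * 10 / p$cl, tolerance = 1e-3)
})

test_that("mass balance holds in the ODE system", {
  p <- typical()
  # eliminated = ke * integral of A_central; check A_depot + A_central +
  # eliminated == dose at the end of a long horizon via fine trapezoid
  g <- seq(0, 72, 0.01)
  central_mg <- conc_profile(p, dose_regimen(0, 10), g[-1]) * p$v / 1000
  eliminated <- p$ke * sum((central_mg[-1] + central_mg[-length(central_mg)]) / 2 * diff(g[-1]))
  depot <- 10 * exp(-p$ka * (max(g) - p$tlag))
  expect_equal(depot + central_mg[length(central_mg)] + eliminated, 10,
               tolerance = 1e-3)
})

test_that("invalid structural inputs are rejected", {
  expect_error(structural_params(ka = -1), "positive")
  expect_error(structural_params(tlag = -0.1), "nonnegative")
  expect_error(dose_regimen(numeric(0)), "at least one")
  expect_error(dose_regimen(c(1, 0), 10), "nondecreasing")
  expect_error(dose_regimen(0, -5), "positive")
  expect_error(conc_profile(typical(), dose_regimen(0, 10), c(1, 1)),
               "strictly increasing")
})
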