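# Estimation-layer tests use small synthetic studies so the whole file runs
# in a few minutes on one core.

make_study <- function(n, seed, pop = default_pop(), ...)
  generate_study(pop, study_design(n_subjects = n, ...), seed = seed)

test_that("omega = 0 objective equals the pooled proportional-error criterion", {
  pop <- default_pop()
  dat <- make_study(6, seed = 2)
  pop0 <- population_params(theta = pop$theta, omega = matrix(0, 3, 3),
                            sigma_prop = pop$sigma_prop)
  res <- foce_i_objective(dat, pop0)
  obs <- dat[dat$evid == 0 & dat$mdv == 0, ]
  pred <- unlist(lapply(split(obs, obs$id), function(s)
    conc_profile(pop$theta, dose_regimen(0, 10), s$time)))
  sig <- pop$sigma_prop
  pooled <- sum((obs$dv - pred)^2 / (sig * pred)^2 + log(sig^2 * pred^2))
  expect_equal(res$ofv, pooled, tolerance = 1e-8)
  expect_equal(res$eta, matrix(0, 6, 3), ignore_attr = TRUE)
})

test_that("FOCE objective approximates the exact marginal likelihood at small IIV", {
  # with modest random effects the linearization is near-exact; compare the
  # per-subject contribution with brute-force Monte Carlo integration of
  # the marginal likelihood over eta (200k prior draws, fixed seed)
  theta <- structural_params()
  om <- omega_from_cv(8, 5, 6, 0.4)
  pop <- population_params(theta = theta, omega = om, sigma_prop = 0.15)
  dat <- make_study(3, seed = 4, pop = pop)
  res <- foce_i_objective(dat, pop)
  set.seed(500)
  L <- t(chol(om))
  draws <- matrix(rnorm(3 * 200000), ncol = 3) %*% t(L)
  for (i in 1:3) {
    obs <- dat[dat$id == i & dat$evid == 0 & dat$mdv == 0, ]
    loglik <- apply(draws, 1, function(e) {
      p <- structural_params(theta$ka * exp(e[1]), theta$v * exp(e[2]),
                             theta$cl * exp(e[3]), theta$tlag)
      f <- conc_profile(p, dose_regimen(0, 10), obs$time)
      -0.5 * sum((obs$dv - f)^2 / (0.15 * f)^2 + log(0.15^2 * f^2))
    })
    m <- max(loglik)
    ofv_exact <- -2 * (m + log(mean(exp(loglik - m))))
    expect_equal(res$ofv_i[i], ofv_exact, tolerance = 0.01 * abs(ofv_exact))
  }
})

test_that("noiseless data at the truth gives a stationary, minimal objective", {
  theta <- structural_params()
  # noiseless data with a small assumed sigma: the data-misfit term then
  # dominates the log-variance term, so the objective is minimal at truth
  pop0 <- population_params(theta = theta, omega = matrix(0, 3, 3),
                            sigma_prop = 0.01)
  dat <- generate_study(pop0, study_design(n_subjects = 8), seed = 1,
                        include_residual = FALSE)
  ofv_at <- function(f_ka = 1, f_cl = 1) {
    p <- population_params(
      theta = structural_params(theta$ka * f_ka, theta$v, theta$cl * f_cl,
                                theta$tlag),
      omega = matrix(0, 3, 3), sigma_prop = 0.01)
    foce_i_objective(dat, p)$ofv
  }
  base <- ofv_at()
  for (f in c(0.9, 0.99, 1.01, 1.1)) {
    expect_gt(ofv_at(f_ka = f), base)
    expect_gt(ofv_at(f_cl = f), base)
  }
})

test_that("objective is invariant to subject relabeling and record order", {
  pop <- default_pop()
  dat <- make_study(7, seed = 6)
  base <- foce_i_objective(dat, pop)$ofv
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  dat2 <- dat
  dat2$id <- perm[dat$id]
  dat2 <- pk_dataset(dat2[order(dat2$id, dat2$time, -dat2$evid), ])
  expect_equal(foce_i_objective(dat2, pop)$ofv, base, tolerance = 1e-8)
})

test_that("likelihood ratio test applies the strict 3.84 cutoff", {
  expect_false(lrt(100, 100 - 3.84, 1)$significant)   # boundary: not strict drop
  expect_true(lrt(100, 100 - 3.85, 1)$significant)
  expect_true(lrt(120, 94.7, 1)$significant)          # drop of 25.3
  expect_false(lrt(100, 100, 1)$significant)
  expect_warning(lrt(90, 100, 1), "higher objective")
  expect_error(lrt(100, 90, 0), "df_added")
})

test_that("adding the lag parameter never worsens, and here improves, the fit", {
  pop <- default_pop()
  dat <- make_study(23, seed = 1)
  fit_lag <- fit_foce(dat, pop, compute_se = FALSE)
  fit_nolag <- fit_foce(dat, pop, estimate_tlag = FALSE, tlag_value = 0,
                        compute_se = FALSE)
  expect_lte(fit_lag$ofv, fit_nolag$ofv + 1e-3)   # nesting inequality
  expect_true(lrt(fit_nolag, fit_lag, 1)$significant)
})

test_that("parameter recovery on a moderate synthetic study", {
  pop <- default_pop()
  dat <- make_study(60, seed = 1)
  fit <- fit_foce(dat, pop, compute_se = TRUE)
  expect_true(fit$convergence)
  th <- fit$estimates$theta
  tr <- pop$theta
  # bounds budget ~ linearization bias (a few %) plus 2-3 sampling SEs of
  # the random-effect mean at this n; Ka carries ~159% CV between subjects
  # so its band is wide
  expect_lt(abs(th$v / tr$v - 1), 0.15)
  expect_lt(abs(th$cl / tr$cl - 1), 0.15)
  expect_lt(abs(th$tlag / tr$tlag - 1), 0.10)
  expect_lt(abs(th$ka / tr$ka - 1), 0.35)
  expect_lt(abs(fit$estimates$sigma_prop / 0.284 - 1), 0.15)
  # Hessian-based relative standard errors exist and are positive
  expect_true(all(is.finite(fit$se[c("ka", "v", "cl", "tlag")])))
  expect_true(all(fit$rse_pct[c("v", "cl", "tlag")] < 25))
})

test_that("sex covariate test: null data not significant, strong effect detected", {
  pop <- default_pop()
  dat <- make_study(23, seed = 3)
  base <- fit_foce(dat, pop, compute_se = FALSE)
  res <- covariate_sex_test(dat, base)
  expect_false(res$cl$significant)
  expect_false(res$v$significant)
  # 30% lower female clearance on a larger study is picked up
  dat_eff <- generate_study(pop, study_design(n_subjects = 60), seed = 5,
                            sex_cl_ratio = 0.7)
  base_eff <- fit_foce(dat_eff, pop, compute_se = FALSE)
  res_eff <- covariate_sex_test(dat_eff, base_eff)
  expect_true(res_eff$cl$significant)
  expect_lt(res_eff$cl$beta, 0)
  # single-sex data is not testable
  dat1 <- generate_study(pop, study_design(n_subjects = 6, sex = "M"), seed = 1)
  fit1 <- fit_foce(dat1, pop, compute_se = FALSE)
  expect_error(covariate_sex_test(dat1, fit1), "one label")
})

test_that("residual diagnostics are calibrated under the correct model", {
  pop <- default_pop()
  dat <- make_study(45, seed = 8)
  fit <- fit_foce(dat, pop, compute_se = FALSE)
  gof <- cwres_and_gof(dat, fit)
  expect_equal(nrow(gof), sum(dat$evid == 0 & dat$mdv == 0))
  expect_lt(abs(mean(gof$cwres)), 0.15)
  expect_lt(abs(var(gof$cwres) - 1), 0.2)
  expect_true(all(is.finite(gof$iwres)))
  # near-zero residuals when refitting noiseless, zero-IIV data at truth
  pop0 <- population_params(omega = matrix(0, 3, 3), sigma_prop = 0.284)
  dat0 <- generate_study(pop0, study_design(n_subjects = 5), seed = 2,
                         include_residual = FALSE)
  obj0 <- foce_i_objective(dat0, pop0)
  expect_lt(max(abs(obj0$eta)), 1e-10)
})

test_that("omitting the lag leaves a systematic early-time residual trend", {
  pop <- default_pop()
  dat <- make_study(30, seed = 10)
  fit_lag <- fit_foce(dat, pop, compute_se = FALSE)
  fit_nolag <- fit_foce(dat, pop, estimate_tlag = FALSE, tlag_value = 0,
                        compute_se = FALSE)
  g_lag <- cwres_and_gof(dat, fit_lag)
  g_nolag <- cwres_and_gof(dat, fit_nolag)
  # the lag signature is a swing in the binned residual means across the
  # absorption phase; summarise by the largest per-time |mean CWRES| there
  early <- function(g) {
    sub <- g[g$time <= 1, ]
    max(abs(tapply(sub$cwres, sub$time, mean)))
  }
  expect_gt(early(g_nolag), early(g_lag) + 0.3)
})

test_that("bootstrap medians track the point estimates and CIs behave", {
  pop <- default_pop()
  dat <- make_study(23, seed = 1)
  fit <- fit_foce(dat, pop, compute_se = FALSE)
  bt <- bootstrap_fit(dat, n_boot = 30, seed = 9, fit = fit)
  expect_gt(bt$n_converged, 15)
  s <- bt$summary
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  for (par in c("v", "cl", "tlag", "sigma")) {
    row <- s[s$parameter == par, ]
    expect_lt(abs(row$median / row$original - 1), 0.10)
  }
})

test_that("VPC self-consistency: observed percentiles sit inside simulated bands", {
  pop <- default_pop()
  dat <- make_study(23, seed = 14)
  v <- vpc(dat, pop, n_sim = 300, seed = 15)
  inside <- mean(v$observed >= v$sim_lower & v$observed <= v$sim_upper)
  expect_gt(inside, 0.80)
  # degenerate population: bands collapse onto the typical curve
  pop0 <- population_params(omega = matrix(0, 3, 3), sigma_prop = 1e-12)
  dat0 <- generate_study(pop0, study_design(n_subjects = 10), seed = 2,
                         include_residual = FALSE)
  v0 <- vpc(dat0, pop0, n_sim = 100, seed = 3)
  typ <- conc_profile(pop0$theta, dose_regimen(0, 10), v0$bins)
  for (k in seq_along(v0$probs))
    expect_equal(unname(v0$sim_median[, k]), typ, tolerance = 1e-6)
})
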