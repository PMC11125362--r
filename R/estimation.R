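#' @useDynLib zolpitox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal: dataset <-> C++ subject list, parameter packing ------------

subjects_for_cpp <- function(data, covariate = NULL, beta = 0) {
  ids <- unique(data$id)
  lapply(ids, function(i) {
    sub <- data[data$id == i, , drop = FALSE]
    obs <- sub[sub$evid == 0L & sub$mdv == 0L, , drop = FALSE]
    dos <- sub[sub$evid == 1L, , drop = FALSE]
    x <- 0
    if (!is.null(covariate)) {
      if (!"sex" %in% names(sub)) stop("dataset has no 'sex' column", call. = FALSE)
      x <- as.numeric(sub$sex[1L] == "F")
    }
    list(t = obs$time, y = obs$dv, dose_t = dos$time, dose_a = dos$amt,
         clm = if (identical(covariate, "cl")) exp(beta * x) else 1,
         vm  = if (identical(covariate, "v"))  exp(beta * x) else 1)
  })
}

# model_config: which pieces are estimated and how
foce_config <- function(estimate_tlag = TRUE, tlag_value = 0,
                        covariate = NULL) {
  if (!is.null(covariate)) covariate <- match.arg(covariate, c("cl", "v"))
  list(estimate_tlag = estimate_tlag, tlag_value = tlag_value,
       covariate = covariate)
}

# pack: log ka, log v, log cl, [log tlag], [beta_cov],
#       log l11, log l22, l32, log l33, log sigma
pack_params <- function(pop, cfg, beta = 0) {
  th <- pop$theta
  L <- omega_factor(pop$omega)
  x <- c(log(th$ka), log(th$v), log(th$cl))
  if (cfg$estimate_tlag) x <- c(x, log(th$tlag))
  if (!is.null(cfg$covariate)) x <- c(x, beta)
  c(x, log(max(L[1, 1], 1e-4)), log(max(L[2, 2], 1e-4)), L[3, 2],
    log(max(L[3, 3], 1e-4)), log(pop$sigma_prop))
}

unpack_params <- function(x, cfg) {
  i <- 4L
  tlag <- if (cfg$estimate_tlag) { v <- exp(x[i]); i <- i + 1L; v } else cfg$tlag_value
  beta <- if (!is.null(cfg$covariate)) { v <- x[i]; i <- i + 1L; v } else 0
  L <- matrix(0, 3, 3)
  L[1, 1] <- exp(x[i]); L[2, 2] <- exp(x[i + 1L])
  L[3, 2] <- x[i + 2L]; L[3, 3] <- exp(x[i + 3L])
  sigma <- exp(x[i + 4L])
  list(theta = c(ka = exp(x[1]), v = exp(x[2]), cl = exp(x[3]), tlag = tlag),
       beta = beta, omega = L %*% t(L), sigma = sigma)
}

param_labels <- function(cfg) {
  lab <- c("ka", "v", "cl")
  if (cfg$estimate_tlag) lab <- c(lab, "tlag")
  if (!is.null(cfg$covariate)) lab <- c(lab, paste0("beta_sex_", cfg$covariate))
  c(lab, "omega_l11", "omega_l22", "omega_l32", "omega_l33", "sigma")
}

#' FOCE-I objective function value
#'
#' Evaluates the first-order-conditional-estimation-with-interaction
#' approximation to -2 log-likelihood for a population model on a dataset.
#' Per subject, the conditional mode of the random effects is found by a
#' damped Gauss-Newton search; the subject's contribution is
#' `log det(C) + r' C^-1 r` with `C = G Omega G' + diag(sigma^2 ipred^2)`,
#' `G` the model gradient in eta at the mode, and
#' `r = y - ipred + G etahat` (residual variance at the conditional
#' prediction — the "interaction"). The `n log(2pi)` constant is omitted,
#' the NONMEM convention, so objective drops are comparable to the usual
#' chi-squared cutoffs.
#'
#' With `omega = 0` the objective degenerates to the pooled
#' proportional-error least-squares criterion at `eta = 0`.
#'
#' @param data A [pk_dataset()].
#' @param pop A [population_params()] object at which to evaluate.
#' @param cfg Internal model configuration (see [fit_foce()] arguments).
#' @param eta_init Optional warm-start matrix of modes (subjects x 3).
#' @return List with `ofv`, per-subject `ofv_i`, conditional modes `eta`,
#'   and `n_fail`.
#' @export
foce_i_objective <- function(data, pop, cfg = foce_config(), eta_init = NULL) {
  stopifnot(inherits(data, "pk_dataset"), inherits(pop, "population_params"))
  if (pop$sigma_prop <= 0) stop("sigma must be > 0 for the likelihood", call. = FALSE)
  subs <- subjects_for_cpp(data, cfg$covariate, 0)
  if (is.null(eta_init)) eta_init <- matrix(0, length(subs), 3)
  th <- c(pop$theta$ka, pop$theta$v, pop$theta$cl, pop$theta$tlag)
  foce_ofv_cpp(subs, th, pop$omega, pop$sigma_prop, eta_init, FALSE)
}

#' Fit the population model by FOCE-I
#'
#' Maximum-likelihood estimation of the hierarchical model (typical values,
#' IIV covariance, proportional error SD) under the FOCE-I approximation.
#' The outer search runs on an unconstrained scale — log typical values,
#' log-Cholesky factor of Omega (Ka independent; Vd/CL correlated block),
#' log sigma — via [stats::nlminb()]; inner conditional modes are
#' warm-started across outer iterations. Standard errors come from the
#' inverse numerical Hessian of the objective at the optimum.
#'
#' @param data A [pk_dataset()].
#' @param init A [population_params()] object of starting values.
#' @param estimate_tlag Estimate the absorption lag? `FALSE` fixes it at
#'   `tlag_value` (the no-lag reduced model used in the lag LRT).
#' @param tlag_value Fixed lag when `estimate_tlag = FALSE`.
#' @param covariate `NULL`, `"cl"` or `"v"`: adds a multiplicative
#'   `exp(beta * female)` sex factor on that parameter.
#' @param compute_se Compute Hessian-based standard errors? Default TRUE.
#' @param control Passed to [stats::nlminb()].
#' @param eta_start Optional subjects x 3 matrix of inner-search starting
#'   modes (used to warm-start bootstrap refits); default zeros. Held fixed
#'   across outer iterations so the objective stays deterministic.
#' @return Object of class `foce_fit`: `estimates` (a
#'   [population_params()]), `ofv`, `beta_sex`, `se` and `rse_pct` (named;
#'   `rse_pct` is the relative standard error of the natural-scale
#'   parameter, Hessian-based), `eta` (conditional modes), `convergence`,
#'   `iterations`, `cfg`, internal `x` and `vcov`.
#' @examples
#' \donttest{
#' dat <- generate_study(population_params(), study_design(), seed = 1)
#' fit <- fit_foce(dat, population_params(), compute_se = FALSE)
#' fit$estimates$theta
#' }
#' @export
fit_foce <- function(data, init = population_params(), estimate_tlag = TRUE,
                     tlag_value = 0, covariate = NULL, compute_se = TRUE,
                     control = list(rel.tol = 1e-10, iter.max = 400),
                     eta_start = NULL) {
  stopifnot(inherits(data, "pk_dataset"), inherits(init, "population_params"))
  cfg <- foce_config(estimate_tlag, tlag_value, covariate)
  subs <- subjects_for_cpp(data, cfg$covariate, 0)
  n_sub <- length(subs)
  # fixed inner start keeps the objective a deterministic function of x
  eta0 <- if (is.null(eta_start)) matrix(0, n_sub, 3) else eta_start
  stopifnot(nrow(eta0) == n_sub)
  sex_ind <- if (!is.null(cfg$covariate))
    vapply(split(data$sex, data$id)[as.character(unique(data$id))],
           function(s) as.numeric(s[1L] == "F"), numeric(1))
  with_cov <- function(beta) {
    if (is.null(cfg$covariate)) return(subs)
    lapply(seq_along(subs), function(k) {
      s <- subs[[k]]
      m <- exp(beta * sex_ind[k])
      if (cfg$covariate == "cl") s$clm <- m else s$vm <- m
      s
    })
  }
  obj <- function(x) {
    pr <- unpack_params(x, cfg)
    if (any(!is.finite(unlist(pr[c("theta", "sigma")])))) return(1e10)
    res <- foce_ofv_cpp(with_cov(pr$beta), unname(pr$theta), pr$omega,
                        pr$sigma, eta0, FALSE)
    if (!is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  x0 <- pack_params(init, cfg)
  opt <- stats::nlminb(x0, obj, control = control)
  # nlminb's "false convergence" is frequent on this objective even at a
  # genuine optimum (inner-problem tolerance leaves ~1e-6 nonsmoothness);
  # verify stationarity by central differences instead of trusting the code
  converged <- opt$convergence == 0L
  if (!converged) {
    g <- vapply(seq_along(opt$par), function(k) {
      h <- 1e-5
      xp <- xm <- opt$par
      xp[k] <- xp[k] + h
      xm[k] <- xm[k] - h
      (obj(xp) - obj(xm)) / (2 * h)
    }, numeric(1))
    converged <- all(is.finite(g)) && max(abs(g)) < 0.1
  }
  pr <- unpack_params(opt$par, cfg)
  fin <- foce_ofv_cpp(with_cov(pr$beta), unname(pr$theta), pr$omega, pr$sigma,
                      eta0, TRUE)
  est <- population_params(
    theta = structural_params(pr$theta[["ka"]], pr$theta[["v"]],
                              pr$theta[["cl"]], pr$theta[["tlag"]]),
    omega = pr$omega, sigma_prop = pr$sigma)
  lab <- param_labels(cfg)
  se <- rse <- stats::setNames(rep(NA_real_, length(lab)), lab)
  vc <- NULL
  if (compute_se) {
    # wide FD steps: the objective carries ~1e-5 inner-solve noise, so
    # narrow steps give an indefinite Hessian; the surface is close to
    # quadratic on the log scale at this width
    H <- tryCatch(stats::optimHess(opt$par, obj,
                                   control = list(ndeps = rep(1e-2, length(opt$par)))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)  # OFV = -2 logL
      if (!is.null(vc) && all(diag(vc) > 0)) {
        se_x <- sqrt(diag(vc))
        se <- stats::setNames(se_x, lab)
        # log-scale SE approximates the natural-scale relative SE
        natural <- !lab %in% c("omega_l32") & !startsWith(lab, "beta_sex")
        rse <- stats::setNames(ifelse(natural, 100 * se_x, NA_real_), lab)
      }
    }
  }
  structure(list(estimates = est, ofv = fin$ofv, beta_sex = pr$beta,
                 se = se, rse_pct = rse, eta = fin$eta,
                 convergence = converged && fin$n_fail == 0L,
                 iterations = opt$iterations, cfg = cfg, x = opt$par,
                 vcov = vc, n_subjects = n_sub),
            class = "foce_fit")
}

#' @export
print.foce_fit <- function(x, ...) {
  th <- x$estimates$theta
  cat(sprintf("FOCE-I fit: OFV %.3f (%d subjects, converged: %s)\n",
              x$ofv, x$n_subjects, x$convergence))
  cat(sprintf("  Ka %.3f 1/h  Vd/F %.2f L  CL/F %.2f L/h  ALAG %.3f h  sigma %.3f\n",
              th$ka, th$v, th$cl, th$tlag, x$estimates$sigma_prop))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `delta_ofv = ofv_reduced - ofv_full`; the addition of `df_added`
#' parameters is significant at the 0.05 level iff the drop strictly
#' exceeds the chi-squared critical value (3.84 for one parameter).
#'
#' @param ofv_reduced,ofv_full Objective function values (or `foce_fit`
#'   objects) of the reduced and full model.
#' @param df_added Number of parameters added in the full model, >= 1.
#' @param alpha Significance level, default 0.05.
#' @return List with `delta_ofv`, `critical`, `significant`.
#' @examples
#' lrt(120.0, 94.7, 1)  # drop of 25.3 >> 3.84
#' @export
lrt <- function(ofv_reduced, ofv_full, df_added = 1, alpha = 0.05) {
  if (inherits(ofv_reduced, "foce_fit")) ofv_reduced <- ofv_reduced$ofv
  if (inherits(ofv_full, "foce_fit")) ofv_full <- ofv_full$ofv
  if (df_added < 1) stop("df_added must be >= 1", call. = FALSE)
  delta <- ofv_reduced - ofv_full
  if (delta < -1e-3)
    warning("full model has a higher objective than the reduced one; ",
            "an optimization likely failed", call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df_added)
  list(delta_ofv = delta, critical = crit, significant = delta > crit)
}

#' Sex covariate test on clearance or volume
#'
#' Refits the model with a multiplicative `exp(beta * female)` factor on
#' CL (and, separately, on V) and compares each against the base fit by
#' likelihood-ratio test.
#'
#' @param data A [pk_dataset()] with a `sex` column holding two levels.
#' @param base_fit A `foce_fit` of the model without the covariate.
#' @return Named list (`cl`, `v`) of lists with `beta`, `delta_ofv`,
#'   `significant`.
#' @export
covariate_sex_test <- function(data, base_fit) {
  stopifnot(inherits(data, "pk_dataset"), inherits(base_fit, "foce_fit"))
  if (!"sex" %in% names(data)) stop("dataset has no 'sex' column", call. = FALSE)
  sex_per_id <- vapply(split(data$sex, data$id), `[`, character(1), 1L)
  if (length(unique(sex_per_id)) < 2L)
    stop("sex covariate not testable: all subjects share one label", call. = FALSE)
  out <- list()
  for (cov in c("cl", "v")) {
    f <- fit_foce(data, init = base_fit$estimates,
                  estimate_tlag = base_fit$cfg$estimate_tlag,
                  tlag_value = base_fit$cfg$tlag_value,
                  covariate = cov, compute_se = FALSE)
    tst <- lrt(base_fit$ofv, f$ofv, 1)
    out[[cov]] <- list(beta = f$beta_sex, delta_ofv = tst$delta_ofv,
                       significant = tst$significant)
  }
  out
}

#' Nonparametric bootstrap of the FOCE-I fit
#'
#' Resamples subjects with replacement `n_boot` times, refits each
#' replicate (warm-started at the original estimates), and summarises each
#' parameter by the median and percentile 95% confidence interval over the
#' converged replicates.
#'
#' @param data A [pk_dataset()] with >= 2 subjects.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for the resampling.
#' @param fit Optional original `foce_fit`; computed if missing.
#' @param init Starting values for the original fit.
#' @return Object of class `boot_result`: `summary` data frame (parameter,
#'   original, median, lower, upper), `n_converged`, `n_boot`, `draws`.
#' @export
bootstrap_fit <- function(data, n_boot = 200, seed = NULL, fit = NULL,
                          init = population_params()) {
  stopifnot(inherits(data, "pk_dataset"))
  ids <- unique(data$id)
  if (length(ids) < 2L) stop("bootstrap needs >= 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) fit <- fit_foce(data, init, compute_se = FALSE)
  natural <- function(f) {
    th <- f$estimates$theta
    om <- f$estimates$omega
    c(ka = th$ka, v = th$v, cl = th$cl, tlag = th$tlag,
      omega2_ka = om[1, 1], omega2_v = om[2, 2], omega2_cl = om[3, 3],
      rho_v_cl = if (om[2, 2] > 0 && om[3, 3] > 0)
        om[2, 3] / sqrt(om[2, 2] * om[3, 3]) else NA_real_,
      sigma = f$estimates$sigma_prop)
  }
  orig <- natural(fit)
  draws <- matrix(NA_real_, n_boot, length(orig),
                  dimnames = list(NULL, names(orig)))
  n_conv <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    reb <- do.call(rbind, lapply(seq_along(take), function(k) {
      sub <- data[data$id == take[k], , drop = FALSE]
      sub$id <- k
      sub
    }))
    reb <- pk_dataset(reb)
    f <- tryCatch(
      fit_foce(reb, init = fit$estimates,
               estimate_tlag = fit$cfg$estimate_tlag,
               tlag_value = fit$cfg$tlag_value, compute_se = FALSE,
               control = list(rel.tol = 1e-6, iter.max = 150),
               eta_start = fit$eta[match(take, ids), , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(f) && f$convergence) {
      draws[b, ] <- natural(f)
      n_conv <- n_conv + 1L
    }
  }
  if (n_conv == 0L) stop("all bootstrap replicates failed to converge", call. = FALSE)
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  structure(list(
    summary = data.frame(parameter = names(orig), original = unname(orig),
                         median = qs[1, ], lower = qs[2, ], upper = qs[3, ]),
    n_converged = n_conv, n_boot = n_boot, draws = draws[ok, , drop = FALSE]),
    class = "boot_result")
}

#' Residual diagnostics (CWRES, IWRES, PRED, IPRED)
#'
#' Per-observation goodness-of-fit table for a converged fit: population
#' prediction (eta = 0), individual prediction at the conditional mode,
#' individual weighted residual `(dv - ipred) / (sigma ipred)`, and the
#' conditional weighted residual — the FOCE-linearized marginal residual
#' decorrelated by the Cholesky factor of the subject's marginal
#' covariance, approximately N(0,1) under a correct model.
#'
#' @param data The [pk_dataset()] that was fitted.
#' @param fit A `foce_fit`.
#' @return Data frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `iwres`, `cwres`.
#' @export
cwres_and_gof <- function(data, fit) {
  stopifnot(inherits(data, "pk_dataset"), inherits(fit, "foce_fit"))
  pr <- unpack_params(fit$x, fit$cfg)
  subs <- subjects_for_cpp(data, fit$cfg$covariate, pr$beta)
  res <- foce_ofv_cpp(subs, unname(pr$theta), pr$omega, pr$sigma,
                      fit$eta, TRUE)
  obs <- data[data$evid == 0L & data$mdv == 0L, , drop = FALSE]
  data.frame(id = obs$id, time = obs$time, dv = obs$dv,
             pred = unlist(res$pred), ipred = unlist(res$ipred),
             iwres = unlist(res$iwres), cwres = unlist(res$cwres))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design (with
#' residual error), computes the 5th/50th/95th percentile of the
#' concentrations in each time bin for the observed data and for every
#' replicate, and returns the observed percentile curves together with the
#' 95% confidence band of each simulated percentile. Default bins: one per
#' nominal sampling time. Bins with no observations are merged with their
#' left neighbour.
#'
#' @param data A [pk_dataset()].
#' @param pop A [population_params()] object to simulate from (usually the
#'   fit estimates).
#' @param n_sim Number of simulated replicates, >= 100.
#' @param seed Optional integer seed.
#' @param bins Optional vector of bin midpoint times; default the unique
#'   observed times.
#' @param probs Percentiles, default `c(0.05, 0.5, 0.95)`.
#' @return Object of class `vpc_result`: `bins`, `observed` (bins x probs
#'   matrix), `sim_lower`/`sim_median`/`sim_upper` (same shape: the 95%
#'   confidence band and median of each percentile across replicates),
#'   `probs`, `n_sim`.
#' @export
vpc <- function(data, pop, n_sim = 1000, seed = NULL, bins = NULL,
                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(data, "pk_dataset"), inherits(pop, "population_params"))
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- data[data$evid == 0L & data$mdv == 0L, , drop = FALSE]
  if (is.null(bins)) bins <- sort(unique(obs$time))
  bin_of <- function(tt) vapply(tt, function(x) which.min(abs(bins - x)), integer(1))
  obs_bin <- bin_of(obs$time)
  keep <- sort(unique(obs_bin))
  bins <- bins[keep]
  obs_bin <- match(obs_bin, keep)
  binned_q <- function(vals, b) {
    out <- matrix(NA_real_, length(bins), length(probs))
    for (k in seq_along(bins))
      out[k, ] <- stats::quantile(vals[b == k], probs = probs, type = 7,
                                  names = FALSE)
    out
  }
  observed <- binned_q(obs$dv, obs_bin)
  # per-subject design (times and doses) reused for every replicate
  ids <- unique(data$id)
  design <- lapply(ids, function(i) {
    sub <- data[data$id == i, , drop = FALSE]
    o <- sub[sub$evid == 0L & sub$mdv == 0L, , drop = FALSE]
    d <- sub[sub$evid == 1L, , drop = FALSE]
    list(times = o$time, regimen = dose_regimen(d$time, d$amt))
  })
  sims <- array(NA_real_, c(n_sim, length(bins), length(probs)))
  for (r in seq_len(n_sim)) {
    inds <- sample_individuals(pop, length(ids))
    dvs <- unlist(lapply(seq_along(ids), function(k) {
      ip <- conc_profile(inds[[k]]$params, design[[k]]$regimen, design[[k]]$times)
      as.numeric(apply_residual_error(ip, pop$sigma_prop))
    }))
    sims[r, , ] <- binned_q(pmax(dvs, 0), obs_bin)
  }
  qs <- function(p) apply(sims, c(2, 3), stats::quantile, probs = p, names = FALSE)
  dimn <- list(sprintf("t%g", bins), sprintf("p%g", 100 * probs))
  observed <- structure(observed, dimnames = dimn)
  structure(list(bins = bins, observed = observed,
                 sim_lower = structure(qs(0.025), dimnames = dimn),
                 sim_median = structure(qs(0.5), dimnames = dimn),
                 sim_upper = structure(qs(0.975), dimnames = dimn),
                 probs = probs, n_sim = n_sim),
            class = "vpc_result")
}
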