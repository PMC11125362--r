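#' Interindividual variance matrix from reported CV percentages
#'
#' Builds the 3x3 log-scale covariance matrix Omega for the random effects
#' (eta_Ka, eta_Vd, eta_CL). Variability is reported as a coefficient of
#' variation in percent; two conventions map CV% to a log-scale variance:
#'
#' * `"exact-lognormal"` (default): `omega^2 = ln(1 + (CV/100)^2)`, the exact
#'   relation for a lognormal variate.
#' * `"sd-equals-cv"`: `omega^2 = (CV/100)^2`, the common reporting shortcut
#'   `CV% = 100 sqrt(omega^2)`.
#'
#' The two differ negligibly below ~30% CV but materially at the ~159% CV
#' of Ka. Vd and CL share a correlation `rho`; Ka is independent.
#'
#' @param cv_ka,cv_v,cv_cl CV% of Ka, Vd/F, CL/F (defaults: final-model
#'   estimates 158.91, 22.10, 32.60).
#' @param rho_v_cl Correlation of eta_Vd and eta_CL in `[-1, 1]`
#'   (default 0.853).
#' @param convention `"exact-lognormal"` or `"sd-equals-cv"`.
#' @return A symmetric positive semidefinite 3x3 matrix with dimnames
#'   `c("ka", "v", "cl")`.
#' @examples
#' omega_from_cv(158.91, 22.10, 32.60, 0.853)
#' @export
omega_from_cv <- function(cv_ka = 158.91, cv_v = 22.10, cv_cl = 32.60,
                          rho_v_cl = 0.853,
                          convention = c("exact-lognormal", "sd-equals-cv")) {
  convention <- match.arg(convention)
  cvs <- c(cv_ka, cv_v, cv_cl)
  if (any(!is.finite(cvs)) || any(cvs < 0)) stop("CVs must be finite and >= 0", call. = FALSE)
  if (!is.finite(rho_v_cl) || abs(rho_v_cl) > 1)
    stop("correlation must lie in [-1, 1]", call. = FALSE)
  w2 <- switch(convention,
               "exact-lognormal" = log(1 + (cvs / 100)^2),
               "sd-equals-cv"    = (cvs / 100)^2)
  om <- diag(w2)
  om[2, 3] <- om[3, 2] <- rho_v_cl * sqrt(w2[2] * w2[3])
  dimnames(om) <- list(c("ka", "v", "cl"), c("ka", "v", "cl"))
  om
}

#' Population pharmacokinetic parameters
#'
#' Typical values plus the stochastic components of the hierarchical model:
#' individual parameters are `P_i = theta * exp(eta_i)` with
#' `eta ~ N(0, Omega)` (lognormal interindividual variability on Ka, Vd/F
#' and CL/F; the lag time carries none), and observations are
#' `DV = IPRED * (1 + eps)` with `eps ~ N(0, sigma^2)` (proportional
#' residual error).
#'
#' Defaults reproduce the final zolpidem model: typical values from
#' [structural_params()], Omega from [omega_from_cv()], and a proportional
#' error SD of 0.284 (28.4% CV).
#'
#' @param theta A [structural_params()] object of typical values.
#' @param omega 3x3 log-scale covariance matrix of (eta_Ka, eta_Vd, eta_CL);
#'   symmetric positive semidefinite.
#' @param sigma_prop Proportional residual error SD (not variance), >= 0.
#' @return An object of class `population_params`.
#' @examples
#' pop <- population_params()
#' pop$sigma_prop
#' @export
population_params <- function(theta = structural_params(),
                              omega = omega_from_cv(),
                              sigma_prop = 0.284) {
  stopifnot(inherits(theta, "structural_params"))
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(3L, 3L))) ||
      !isTRUE(all.equal(omega, t(omega), tolerance = 1e-10)))
    stop("omega must be a symmetric 3x3 matrix", call. = FALSE)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("omega must be positive semidefinite", call. = FALSE)
  if (!is.numeric(sigma_prop) || length(sigma_prop) != 1L || sigma_prop < 0)
    stop("sigma_prop must be a single nonnegative number", call. = FALSE)
  structure(list(theta = theta, omega = omega, sigma_prop = sigma_prop),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population PK parameters\nTypical values:\n")
  print(x$theta)
  cat("IIV covariance (log scale, Ka/Vd/CL):\n")
  print(round(x$omega, 5))
  cat(sprintf("Proportional residual error SD: %.4g\n", x$sigma_prop))
  invisible(x)
}

# Lower-triangular square root; tolerates PSD-but-singular omega.
omega_factor <- function(omega) {
  L <- tryCatch(t(chol(omega)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(omega, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("omega is not positive semidefinite; cannot factorize", call. = FALSE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(omega))
}

#' Sample individuals from the population model
#'
#' Draws `n` independent random-effect vectors `eta ~ N(0, Omega)` through a
#' lower-triangular square root of Omega (subjects in the outer loop order,
#' eta components inner) and realises each subject's structural parameters
#' as `theta * exp(eta)`. The lag time is copied from the typical value.
#' Because of the exponential transform the *median* realized parameter
#' equals its typical value.
#'
#' @param pop A [population_params()] object.
#' @param n Number of subjects, >= 1.
#' @param seed Optional integer seed; draws are reproducible given it.
#' @return A list of length `n`; each element has `id`, `eta` (named
#'   3-vector) and `params` (a [structural_params()] object).
#' @examples
#' ind <- sample_individuals(population_params(), 3, seed = 42)
#' ind[[1]]$params
#' @export
sample_individuals <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  L <- omega_factor(pop$omega)
  z <- matrix(stats::rnorm(n * 3L), nrow = n, ncol = 3L, byrow = TRUE)
  eta <- z %*% t(L)
  colnames(eta) <- c("ka", "v", "cl")
  th <- pop$theta
  lapply(seq_len(n), function(i) {
    e <- eta[i, ]
    list(id = i, eta = e,
         params = structural_params(ka = th$ka * exp(e[["ka"]]),
                                    v = th$v * exp(e[["v"]]),
                                    cl = th$cl * exp(e[["cl"]]),
                                    tlag = th$tlag))
  })
}

#' Apply proportional residual error to predicted concentrations
#'
#' `DV = IPRED * (1 + eps)`, `eps ~ N(0, sigma^2)` i.i.d. Predictions of
#' zero stay exactly zero (the error is multiplicative). The raw output may
#' contain negative values in the far tail; callers that need physical
#' concentrations truncate (see [generate_study()]).
#'
#' @param ipred Nonnegative predicted concentrations (ng/mL).
#' @param sigma_prop Residual error SD, >= 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of observed concentrations with attribute
#'   `n_negative`, the count of negative draws.
#' @export
apply_residual_error <- function(ipred, sigma_prop, seed = NULL) {
  if (any(!is.finite(ipred)) || any(ipred < 0))
    stop("ipred must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(sigma_prop) || length(sigma_prop) != 1L || sigma_prop < 0)
    stop("sigma_prop must be a single nonnegative number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dv <- ipred * (1 + stats::rnorm(length(ipred), sd = sigma_prop))
  attr(dv, "n_negative") <- sum(dv < 0)
  dv
}

#' Read population parameters from a key-value config file
#'
#' Plain-text `key = value` lines (or `key: value`), `#` comments allowed.
#' Recognised keys: `ka`, `v`, `cl`, `tlag`, `cv_ka`, `cv_v`, `cv_cl`,
#' `rho_v_cl`, `sigma_prop`, `cv_convention` (`exact-lognormal` or
#' `sd-equals-cv`). Missing keys keep the package defaults.
#'
#' @param path Path to the config file.
#' @return A [population_params()] object.
#' @export
read_popparams_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable config line: '", ln, "'", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  num <- function(key, default) if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  conv <- if (is.null(kv[["cv_convention"]])) "exact-lognormal" else kv[["cv_convention"]]
  population_params(
    theta = structural_params(ka = num("ka", 5.41), v = num("v", 61.7),
                              cl = num("cl", 16.9), tlag = num("tlag", 0.394)),
    omega = omega_from_cv(num("cv_ka", 158.91), num("cv_v", 22.10),
                          num("cv_cl", 32.60), num("rho_v_cl", 0.853),
                          convention = conv),
    sigma_prop = num("sigma_prop", 0.284))
}
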