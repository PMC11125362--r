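#' Structural pharmacokinetic parameters
#'
#' Bundles the four fixed-effect constants of the one-compartment model with
#' first-order absorption, first-order elimination, and an absorption lag
#' time: absorption rate constant `ka` (1/h), apparent volume of distribution
#' `v` (Vd/F, L), apparent clearance `cl` (CL/F, L/h), and lag time `tlag`
#' (h). The elimination rate constant `ke = cl / v` is derived.
#'
#' The defaults are the typical values of the final zolpidem population model
#' (Ka 5.41 1/h, Vd/F 61.7 L, CL/F 16.9 L/h, ALAG 0.394 h).
#'
#' @param ka Absorption rate constant (1/h), > 0.
#' @param v Apparent volume of distribution Vd/F (L), > 0.
#' @param cl Apparent clearance CL/F (L/h), > 0.
#' @param tlag Absorption lag time (h), >= 0.
#' @return An object of class `structural_params`.
#' @examples
#' p <- structural_params()
#' p$ke  # elimination rate constant, 1/h
#' @export
structural_params <- function(ka = 5.41, v = 61.7, cl = 16.9, tlag = 0.394) {
  for (nm in c("ka", "v", "cl", "tlag")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (ka <= 0 || v <= 0 || cl <= 0)
    stop("ka, v and cl must be strictly positive", call. = FALSE)
  if (tlag < 0) stop("tlag must be nonnegative", call. = FALSE)
  structure(list(ka = ka, v = v, cl = cl, tlag = tlag, ke = cl / v),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("One-compartment oral PK parameters (apparent):\n")
  cat(sprintf("  Ka   %8.4g 1/h\n  Vd/F %8.4g L\n  CL/F %8.4g L/h\n  ALAG %8.4g h\n  ke   %8.4g 1/h (CL/V)\n",
              x$ka, x$v, x$cl, x$tlag, x$ke))
  invisible(x)
}

#' Dosing regimen
#'
#' An ordered set of oral bolus dose events. Amounts are in mg; a single
#' ingestion of several tablets is one event with `amount = strength *
#' n_tablets`.
#'
#' @param times Dose times (h), nonnegative and nondecreasing.
#' @param amounts Dose amounts (mg), strictly positive; recycled to
#'   `length(times)`.
#' @return An object of class `dose_regimen`: a data frame with columns
#'   `time` and `amount`.
#' @examples
#' dose_regimen(0, 280)            # 28 tablets of 10 mg at t = 0
#' dose_regimen(c(0, 12), 10)      # 10 mg at 0 h and 12 h
#' @export
dose_regimen <- function(times = 0, amounts = 10) {
  if (length(times) < 1L) stop("regimen must contain at least one dose", call. = FALSE)
  amounts <- rep_len(amounts, length(times))
  if (any(!is.finite(times)) || any(times < 0))
    stop("dose times must be finite and nonnegative", call. = FALSE)
  if (is.unsorted(times)) stop("dose times must be nondecreasing", call. = FALSE)
  if (any(!is.finite(amounts)) || any(amounts <= 0))
    stop("dose amounts must be finite and positive", call. = FALSE)
  structure(data.frame(time = as.numeric(times), amount = as.numeric(amounts)),
            class = c("dose_regimen", "data.frame"))
}

total_dose <- function(regimen) sum(regimen$amount)

assert_time_grid <- function(times) {
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop("time grid must be finite and nonnegative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  invisible(times)
}

#' Concentration after a single oral dose
#'
#' Closed-form solution of the one-compartment model with first-order
#' absorption and elimination and absorption lag: for `tau = t - tlag > 0`,
#'
#' \deqn{C(t) = 1000 \frac{D\,k_a}{V (k_a - k_e)}
#'   \left(e^{-k_e \tau} - e^{-k_a \tau}\right),\quad k_e = CL/V,}
#'
#' and 0 before the lag time. The factor 1000 converts mg/L to ng/mL. When
#' `ka` and `ke` coincide to within a relative 1e-8 the continuous limit
#' `1000 (D/V) ke tau exp(-ke tau)` is used instead to avoid cancellation.
#'
#' @param p A [structural_params()] object.
#' @param dose Dose (mg), > 0.
#' @param t Time(s) since dosing (h), >= 0. Vectorised.
#' @return Concentration(s) in ng/mL.
#' @examples
#' p <- structural_params()
#' conc_single_dose(p, 10, c(0.3, 1, 4, 12))
#' @export
conc_single_dose <- function(p, dose, t) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("dose must be a single positive number", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and >= 0", call. = FALSE)
  ke <- p$ke
  tau <- t - p$tlag
  out <- numeric(length(t))
  on_ <- tau > 0
  if (any(on_)) {
    tt <- tau[on_]
    if (abs(p$ka - ke) < 1e-8 * ke) {
      out[on_] <- 1000 * (dose / p$v) * ke * tt * exp(-ke * tt)
    } else {
      out[on_] <- 1000 * dose * p$ka / (p$v * (p$ka - ke)) *
        (exp(-ke * tt) - exp(-p$ka * tt))
    }
  }
  out
}

#' Concentration profile under a dosing regimen
#'
#' Superposes the closed-form single-dose solution over all dose events
#' (the model is linear, so multiple doses add). Each event's absorption
#' lag starts at its own dose time.
#'
#' @param p A [structural_params()] object.
#' @param regimen A [dose_regimen()].
#' @param times Evaluation times (h), strictly increasing.
#' @return Numeric vector of concentrations (ng/mL), one per time.
#' @examples
#' p <- structural_params()
#' conc_profile(p, dose_regimen(0, 280), c(0.5, 1, 2, 6))
#' @export
conc_profile <- function(p, regimen, times) {
  stopifnot(inherits(regimen, "dose_regimen"))
  assert_time_grid(times)
  out <- numeric(length(times))
  for (i in seq_len(nrow(regimen))) {
    after <- times >= regimen$time[i]
    if (any(after))
      out[after] <- out[after] +
        conc_single_dose(p, regimen$amount[i], times[after] - regimen$time[i])
  }
  out
}

#' Time and magnitude of the single-dose peak
#'
#' Closed-form peak of the biexponential: `tmax = tlag + ln(ka/ke)/(ka - ke)`
#' (limit `tlag + 1/ke` when `ka = ke`), with `cmax` the concentration there.
#' Dose scales `cmax` linearly and leaves `tmax` unchanged.
#'
#' @inheritParams conc_single_dose
#' @return A list with elements `tmax` (h) and `cmax` (ng/mL).
#' @examples
#' typical_tmax_cmax(structural_params(), 10)
#' @export
typical_tmax_cmax <- function(p, dose) {
  stopifnot(inherits(p, "structural_params"))
  ke <- p$ke
  tmax <- if (abs(p$ka - ke) < 1e-8 * ke) p$tlag + 1 / ke
          else p$tlag + log(p$ka / ke) / (p$ka - ke)
  list(tmax = tmax, cmax = conc_single_dose(p, dose, tmax))
}

#' ODE-integration oracle for the concentration profile
#'
#' Numerically integrates the depot/central two-state system
#' `dA_depot/dt = -ka A_depot`, `dA_central/dt = ka A_depot - ke A_central`
#' with each dose entering the depot as a bolus at its lagged time, and
#' returns `1000 A_central / v`. Exists as an independent cross-check of
#' [conc_profile()]; the closed form is the production evaluator.
#'
#' @inheritParams conc_profile
#' @param atol,rtol Absolute/relative integrator tolerances passed to
#'   [deSolve::lsoda()].
#' @return Numeric vector of concentrations (ng/mL) at `times`.
#' @export
ode_oracle <- function(p, regimen, times, atol = 1e-12, rtol = 1e-10) {
  stopifnot(inherits(p, "structural_params"), inherits(regimen, "dose_regimen"))
  assert_time_grid(times)
  rhs <- function(t, y, parms) {
    list(c(-parms$ka * y[1], parms$ka * y[1] - parms$ke * y[2]))
  }
  events <- data.frame(var = "depot", time = regimen$time + p$tlag,
                       value = regimen$amount, method = "add")
  tout <- sort(unique(c(0, times, events$time)))
  sol <- deSolve::lsoda(c(depot = 0, central = 0), times = tout, func = rhs,
                        parms = list(ka = p$ka, ke = p$ke),
                        events = list(data = events), atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed", call. = FALSE)
  central <- sol[match(times, sol[, "time"]), "central"]
  unname(1000 * central / p$v)
}
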