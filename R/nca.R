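#' Linear-up/log-down AUC
#'
#' Trapezoidal area under the concentration-time curve using the linear
#' rule on rising (or flat, or zero-touching) segments and the logarithmic
#' rule `(c1 - c2) * dt / ln(c1/c2)` on strictly declining segments with
#' both endpoints positive.
#'
#' @param times Strictly increasing sampling times (h).
#' @param concs Nonnegative concentrations (ng/mL), same length.
#' @return AUC over the observed span (ng*h/mL).
#' @examples
#' auc_linuplogdown(c(0, 1, 2), c(0, 100, 50))  # 50 + 72.13
#' @export
auc_linuplogdown <- function(times, concs) {
  if (length(times) != length(concs) || length(times) < 2L)
    stop("times and concs must be equal-length vectors (n >= 2)", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(concs)) || any(concs < 0))
    stop("concentrations must be finite and nonnegative", call. = FALSE)
  c1 <- concs[-length(concs)]
  c2 <- concs[-1L]
  dt <- diff(times)
  logdown <- c2 < c1 & c2 > 0
  seg <- ifelse(logdown, (c1 - c2) * dt / log(c1 / c2), (c1 + c2) / 2 * dt)
  sum(seg)
}

#' Terminal slope (lambda z) of a concentration profile
#'
#' Log-linear regression of `ln(conc)` on time over the terminal phase.
#' The point set is chosen automatically: among all trailing subsets of at
#' least 3 positive concentrations strictly after the observed peak (the
#' Cmax point itself excluded), the subset maximising the adjusted R^2 of
#' the regression is used — the dominant convention in NCA software.
#'
#' @inheritParams auc_linuplogdown
#' @return List with `lambda_z` (1/h), `n_points`, `adj_r2`, and
#'   `t_first_used` (earliest time in the selected set); all `NA` when
#'   fewer than 3 usable points exist.
#' @examples
#' t <- c(4, 6, 8, 12); fit_lambda_z(c(0, 1, 2, t), c(0, 80, 100, 100 * exp(-0.3 * t)))
#' @export
fit_lambda_z <- function(times, concs) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  imax <- which.max(concs)
  cand <- which(seq_along(concs) > imax & concs > 0)
  none <- list(lambda_z = NA_real_, n_points = NA_integer_, adj_r2 = NA_real_,
               t_first_used = NA_real_)
  if (length(cand) < 3L) return(none)
  fits <- lapply(3:length(cand), function(k) {
    idx <- utils::tail(cand, k)
    fit <- stats::lm.fit(cbind(1, times[idx]), log(concs[idx]))
    slope <- unname(fit$coefficients[2L])
    y <- log(concs[idx])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    list(lambda_z = -slope, n_points = k, adj_r2 = adj,
         t_first_used = times[idx[1L]])
  })
  fits <- Filter(function(f) is.finite(f$adj_r2) && f$lambda_z > 0, fits)
  if (length(fits) == 0L) return(none)
  best_adj <- max(vapply(fits, `[[`, numeric(1), "adj_r2"))
  # near-ties (within 1e-4) resolved toward the larger point set
  fits <- Filter(function(f) f$adj_r2 >= best_adj - 1e-4, fits)
  fits[[which.max(vapply(fits, `[[`, numeric(1), "n_points"))]]
}

#' Non-compartmental analysis of one concentration profile
#'
#' Computes the standard exposure metrics from observed (or simulated)
#' concentrations: Cmax and Tmax read directly off the data; AUC to the
#' last observation by the linear-up/log-down rule; lambda z by best
#' adjusted-R^2 terminal regression; and the derived quantities
#' `auc_inf = auc_last + c_last / lambda_z` (c_last = last positive
#' concentration), `half_life = ln(2)/lambda_z`,
#' `cl_f = 1000 * dose / auc_inf` (L/h, the factor 1000 reconciling mg
#' doses with ng*h/mL areas) and `vd_f = cl_f / lambda_z` (L).
#'
#' @inheritParams auc_linuplogdown
#' @param dose Administered dose (mg), > 0.
#' @return Object of class `nca_result`: list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `n_lambda_points`, `adj_r2`,
#'   `half_life`, `cl_f`, `vd_f`. Fields downstream of lambda z are `NA`
#'   when the terminal slope is not estimable.
#' @examples
#' p <- structural_params()
#' tt <- seq(0, 48, 0.1)
#' nca_params(tt, conc_single_dose(p, 10, tt), dose = 10)
#' @export
nca_params <- function(times, concs, dose) {
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("dose must be a single positive number", call. = FALSE)
  imax <- which.max(concs)
  lz <- fit_lambda_z(times, concs)
  auc_last <- auc_linuplogdown(times, concs)
  pos <- which(concs > 0)
  c_last <- if (length(pos)) concs[max(pos)] else 0
  if (is.na(lz$lambda_z)) {
    auc_inf <- half_life <- cl_f <- vd_f <- NA_real_
  } else {
    auc_inf <- auc_last + c_last / lz$lambda_z
    half_life <- log(2) / lz$lambda_z
    cl_f <- 1000 * dose / auc_inf
    vd_f <- cl_f / lz$lambda_z
  }
  structure(list(cmax = concs[imax], tmax = times[imax], auc_last = auc_last,
                 auc_inf = auc_inf, lambda_z = lz$lambda_z,
                 n_lambda_points = lz$n_points, adj_r2 = lz$adj_r2,
                 half_life = half_life, cl_f = cl_f, vd_f = vd_f),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(paste0("NCA: Cmax %.4g ng/mL at Tmax %.3g h; AUClast %.5g, ",
                     "AUCinf %.5g ng*h/mL\n     lambda_z %.4g 1/h (n=%s, adjR2=%.4g), ",
                     "t1/2 %.3g h, CL/F %.4g L/h, Vd/F %.4g L\n"),
              x$cmax, x$tmax, x$auc_last, x$auc_inf, x$lambda_z,
              format(x$n_lambda_points), x$adj_r2, x$half_life, x$cl_f, x$vd_f))
  invisible(x)
}

#' Per-subject NCA of a long-format dataset
#'
#' Runs [nca_params()] on each subject's observation records of a
#' [pk_dataset()] (dose taken from the subject's first dose record;
#' records with `mdv = 1` are excluded).
#'
#' @param data A [pk_dataset()].
#' @return Data frame with one row per subject and the `nca_result` fields
#'   as columns.
#' @export
nca_by_subject <- function(data) {
  stopifnot(inherits(data, "pk_dataset"))
  ids <- unique(data$id)
  rows <- lapply(ids, function(i) {
    sub <- data[data$id == i, , drop = FALSE]
    dose <- sub$amt[sub$evid == 1L][1L]
    obs <- sub[sub$evid == 0L & sub$mdv == 0L, , drop = FALSE]
    res <- nca_params(obs$time, obs$dv, dose)
    data.frame(id = i, cmax = res$cmax, tmax = res$tmax,
               auc_last = res$auc_last, auc_inf = res$auc_inf,
               lambda_z = res$lambda_z, half_life = res$half_life,
               cl_f = res$cl_f, vd_f = res$vd_f)
  })
  do.call(rbind, rows)
}
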