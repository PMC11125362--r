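#' Long-format pharmacokinetic dataset
#'
#' The NONMEM-style long format used throughout the estimation layer: one
#' row per event with columns `id`, `time` (h), `dv` (ng/mL, `NA` on dose
#' rows), `amt` (mg, `NA` on observation rows), `evid` (0 = observation,
#' 1 = dose) and `mdv` (1 = exclude from the likelihood). Optional extra
#' columns (e.g. `sex`) are preserved.
#'
#' Invariants checked: every subject has at least one dose record; no
#' observation precedes a subject's first dose; `dv` present exactly on
#' usable observation rows.
#'
#' @param df A data frame with the columns above (case-insensitive names).
#' @return The validated data frame with class `pk_dataset`.
#' @export
pk_dataset <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("id", "time", "dv", "amt", "evid", "mdv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$evid %in% c(0L, 1L)))
    stop("evid must be 0 (observation) or 1 (dose)", call. = FALSE)
  if (!all(df$mdv %in% c(0L, 1L)))
    stop("mdv must be 0 or 1", call. = FALSE)
  for (i in unique(df$id)) {
    sub <- df[df$id == i, , drop = FALSE]
    doses <- sub[sub$evid == 1L, , drop = FALSE]
    if (nrow(doses) == 0L)
      stop("subject ", i, " has no dose record", call. = FALSE)
    if (any(sub$time[sub$evid == 0L] < min(doses$time)))
      stop("subject ", i, " has observations before the first dose", call. = FALSE)
    if (any(is.na(doses$amt) | doses$amt <= 0))
      stop("subject ", i, " has a dose record without a positive amt", call. = FALSE)
  }
  if (any(df$evid == 0L & df$mdv == 0L & !is.finite(df$dv)))
    stop("usable observation rows (evid 0, mdv 0) must carry a dv", call. = FALSE)
  class(df) <- c("pk_dataset", "data.frame")
  df
}

#' Study design for the synthetic single-dose study
#'
#' Describes the rich-sampling single-oral-dose design the synthetic data
#' generator emulates: one 10 mg dose at time 0 and samples pre-dose and at
#' 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12 h, for 23 subjects
#' (12 male, 11 female) by default.
#'
#' @param n_subjects Number of subjects, >= 1. Default 23.
#' @param dose Dose (mg). Default 10.
#' @param times Sampling times (h), strictly increasing from 0.
#' @param sex Optional character vector of per-subject labels recycled to
#'   `n_subjects`; default assigns 12 `"M"` then 11 `"F"` when
#'   `n_subjects = 23`, else alternates.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 23, dose = 10,
                         times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12),
                         sex = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("sampling times must start at 0 and increase strictly", call. = FALSE)
  if (is.null(sex)) {
    sex <- if (n_subjects == 23L) c(rep("M", 12), rep("F", 11))
           else rep_len(c("M", "F"), n_subjects)
  } else sex <- rep_len(sex, n_subjects)
  structure(list(n_subjects = as.integer(n_subjects), dose = dose,
                 times = times, sex = sex), class = "study_design")
}

#' Generate a synthetic single-dose PK study
#'
#' Simulates a complete long-format dataset under the population model at
#' the given design: per subject one dose record at t = 0 and observation
#' records at the design times, with concentrations drawn with
#' interindividual variability and (by default) proportional residual
#' error. The pre-dose sample is kept as a zero-concentration record with
#' `mdv = 1` — a hard zero is incompatible with a proportional error
#' likelihood. Rare negative error draws are truncated to 0 and counted in
#' attribute `n_truncated`.
#'
#' No sex effect is simulated unless `sex_cl_ratio` differs from 1, in
#' which case female subjects' clearance is multiplied by it.
#'
#' @param pop A [population_params()] object (truth).
#' @param design A [study_design()].
#' @param seed Optional integer seed.
#' @param include_residual Add residual error to observations? Default TRUE.
#' @param sex_cl_ratio Multiplicative clearance factor for `"F"` subjects.
#' @return A [pk_dataset()] with extra column `sex`.
#' @examples
#' dat <- generate_study(population_params(), study_design(), seed = 11)
#' head(dat)
#' @export
generate_study <- function(pop, design = study_design(), seed = NULL,
                           include_residual = TRUE, sex_cl_ratio = 1) {
  stopifnot(inherits(pop, "population_params"), inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  individuals <- sample_individuals(pop, design$n_subjects)
  obs_times <- design$times[design$times > 0]
  regimen <- dose_regimen(0, design$dose)
  n_trunc <- 0L
  rows <- lapply(seq_along(individuals), function(i) {
    p <- individuals[[i]]$params
    if (design$sex[i] == "F" && sex_cl_ratio != 1)
      p <- structural_params(p$ka, p$v, p$cl * sex_cl_ratio, p$tlag)
    ipred <- conc_profile(p, regimen, obs_times)
    dv <- if (include_residual) apply_residual_error(ipred, pop$sigma_prop) else ipred
    n_trunc <<- n_trunc + sum(dv < 0)
    dv <- pmax(dv, 0)
    # zero concentrations (pre-absorption samples, truncated draws) cannot
    # enter a proportional-error likelihood; keep the record, flag mdv = 1
    rbind(
      data.frame(id = i, time = 0, dv = NA_real_, amt = design$dose,
                 evid = 1L, mdv = 1L, sex = design$sex[i]),
      data.frame(id = i, time = 0, dv = 0, amt = NA_real_,
                 evid = 0L, mdv = 1L, sex = design$sex[i]),
      data.frame(id = i, time = obs_times, dv = as.numeric(dv), amt = NA_real_,
                 evid = 0L, mdv = ifelse(dv > 0, 0L, 1L),
                 sex = design$sex[i]))
  })
  out <- pk_dataset(do.call(rbind, rows))
  attr(out, "n_truncated") <- n_trunc
  rownames(out) <- NULL
  out
}

#' Read / write long-format PK datasets
#'
#' CSV dialect: header `ID,TIME,DV,AMT,EVID,MDV` (case-insensitive, extra
#' columns kept), missing `DV`/`AMT` written and read as `"."`. The round
#' trip `write_dataset()` then `read_dataset()` is lossless.
#'
#' @param path File path.
#' @return `read_dataset()` returns a [pk_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ".")
  names(df) <- tolower(names(df))
  need <- c("id", "time", "dv", "amt", "evid", "mdv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("file ", path, " lacks column(s): ",
         paste(toupper(missing_cols), collapse = ", "), call. = FALSE)
  for (col in c("time", "dv", "amt")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop("non-numeric ", toupper(col), " at data row ", bad[1L], call. = FALSE)
      df[[col]] <- as.numeric(v)
    }
  }
  for (col in c("evid", "mdv")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    if (length(bad))
      stop("malformed ", toupper(col), " value at data row ", bad[1L], call. = FALSE)
    df[[col]] <- v
  }
  pk_dataset(df)
}

#' @rdname read_dataset
#' @param data A [pk_dataset()].
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  out <- as.data.frame(data)
  names(out) <- toupper(names(out))
  utils::write.csv(out, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}
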