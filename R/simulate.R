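#' Default simulation time grid
#'
#' Dense sampling (0.02 h steps) up to 4 h to resolve the absorption peak,
#' then sparser 0.25 h steps out to the horizon. The grid contains the
#' clinical rich-sampling times 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4 h as a
#' subset, so simulated profiles can be read off at the study design times.
#'
#' @param t_max Grid horizon (h), > 4. Default 24 h, beyond nine typical
#'   elimination half-lives.
#' @return Strictly increasing numeric vector of times starting at 0.
#' @examples
#' g <- default_time_grid()
#' range(g); max(diff(g[g <= 4]))
#' @export
default_time_grid <- function(t_max = 24) {
  if (!is.numeric(t_max) || t_max <= 4) stop("t_max must exceed 4 h", call. = FALSE)
  clinical <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4)
  sort(unique(round(c(seq(0, 4, by = 0.02), clinical,
                      seq(4.25, t_max, by = 0.25)), 10)))
}

#' Monte Carlo simulation of population concentration profiles
#'
#' Samples `n` individuals from the population model and evaluates each
#' subject's closed-form concentration profile on the grid. Residual
#' (assay) error is off by default: the simulator describes the smooth
#' individual-predicted curve of an unobserved patient; turn it on to
#' emulate measured concentrations (as the VPC does).
#'
#' @param pop A [population_params()] object.
#' @param regimen A [dose_regimen()].
#' @param grid Time grid (h); default [default_time_grid()].
#' @param n Number of simulated subjects, >= 1.
#' @param seed Optional integer seed; results are reproducible given it.
#' @param include_residual Apply proportional residual error to the
#'   concentrations? Default `FALSE`.
#' @return An object of class `simulation_result`: list with `grid`, `conc`
#'   (an `n` x `length(grid)` matrix, ng/mL), `individuals`, `regimen`,
#'   `seed`, `residual_included`.
#' @examples
#' sim <- simulate_population(population_params(), dose_regimen(0, 10),
#'                            n = 20, seed = 7)
#' dim(sim$conc)
#' @export
simulate_population <- function(pop, regimen, grid = default_time_grid(),
                                n, seed = NULL, include_residual = FALSE) {
  stopifnot(inherits(pop, "population_params"), inherits(regimen, "dose_regimen"))
  assert_time_grid(grid)
  if (!is.null(seed)) set.seed(seed)
  individuals <- sample_individuals(pop, n)
  conc <- t(vapply(individuals,
                   function(ind) conc_profile(ind$params, regimen, grid),
                   numeric(length(grid))))
  if (include_residual)
    conc <- matrix(apply_residual_error(as.vector(conc), pop$sigma_prop),
                   nrow = nrow(conc))
  structure(list(grid = grid, conc = conc, individuals = individuals,
                 regimen = regimen, seed = seed,
                 residual_included = include_residual),
            class = "simulation_result")
}

#' Pointwise percentile bands of a simulated population
#'
#' Computes quantiles across subjects at every grid time, using the
#' linear-interpolation quantile definition ([stats::quantile()] type 7).
#'
#' @param sim A `simulation_result`.
#' @param probs Probabilities, default `c(0.05, 0.5, 0.95)`.
#' @return Object of class `percentile_bands`: list with `grid`, `probs`,
#'   and `bands`, a `length(probs)` x `length(grid)` matrix with one row per
#'   probability (rows ordered with `probs`).
#' @export
percentile_bands <- function(sim, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(sim, "simulation_result"))
  if (length(probs) < 1L || any(probs < 0) || any(probs > 1))
    stop("probs must be a nonempty vector in [0, 1]", call. = FALSE)
  ord <- order(probs)
  probs <- probs[ord]
  bands <- apply(sim$conc, 2L, stats::quantile, probs = probs, type = 7,
                 names = FALSE)
  bands <- matrix(bands, nrow = length(probs))
  rownames(bands) <- sprintf("p%g", 100 * probs)
  structure(list(grid = sim$grid, probs = probs, bands = bands),
            class = "percentile_bands")
}

#' Concentration summary at an arbitrary time
#'
#' Linearly interpolates the percentile bands at a query time, answering
#' "what is the plasma concentration now, with its uncertainty band".
#'
#' @param sim A `simulation_result`.
#' @param t_query Query time (h), within the span of the grid.
#' @param probs Band probabilities, default `c(0.05, 0.5, 0.95)`.
#' @return Named numeric vector: one interpolated concentration per
#'   probability (ng/mL).
#' @export
concentration_at <- function(sim, t_query, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(sim, "simulation_result"))
  if (!is.numeric(t_query) || length(t_query) != 1L ||
      t_query < min(sim$grid) || t_query > max(sim$grid))
    stop("t_query must lie within the simulated time span", call. = FALSE)
  pb <- percentile_bands(sim, probs)
  out <- apply(pb$bands, 1L, function(b) stats::approx(pb$grid, b, xout = t_query)$y)
  names(out) <- rownames(pb$bands)
  out
}
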