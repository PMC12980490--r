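#' Define a synthetic ATD scenario
#'
#' A scenario states the ground truth of a simulated drift-tube
#' acquisition: one entry per component giving its ion count and either its
#' mobility K (m^2 V^-1 s^-1, converted to a mean arrival time through
#' t = L^2/(K dV) + t0) or a fixed center in seconds. Component variances
#' are placed on the broadening-physics infimum [sigma2_min()] times a
#' per-component slack factor m >= 1.
#'
#' @param n_ions Numeric vector of per-component ion counts.
#' @param mobility Per-component mobilities (m^2 V^-1 s^-1), or `NULL` if
#'   `center` is given.
#' @param center Per-component mean arrival times in seconds, or `NULL` if
#'   `mobility` is given.
#' @param charge Integer charge state.
#' @param cfg An [instrument_config()].
#' @param noise `"poisson"` (counting noise, default), `"gaussian"`, or
#'   `"none"`.
#' @param gaussian_scale Noise sd in counts for `noise = "gaussian"`.
#' @param slack Per-component variance multiplier m >= 1 (recycled).
#' @param dead_time Field-free transit time t0 in seconds added to every
#'   center computed from a mobility.
#' @param background Optional `list(amplitude=, center=, sd=)` adding a
#'   broad low Gaussian of contaminating ions (not part of the truth).
#' @param prior A [prior_config()] (for the ions-per-count proportionality).
#' @return Object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_ions, mobility = NULL, center = NULL,
                         charge = 1L, cfg = instrument_config(),
                         noise = c("poisson", "gaussian", "none"),
                         gaussian_scale = NULL, slack = 1,
                         dead_time = 0, background = NULL,
                         prior = prior_config()) {
  noise <- match.arg(noise)
  k <- length(n_ions)
  if (k < 1L) stop("sim_scenario: need at least one component")
  if (is.null(mobility) == is.null(center))
    stop("sim_scenario: give exactly one of 'mobility' or 'center'")
  if (!is.null(mobility) && length(mobility) != k)
    stop("sim_scenario: 'mobility' length must match 'n_ions'")
  if (!is.null(center) && length(center) != k)
    stop("sim_scenario: 'center' length must match 'n_ions'")
  slack <- rep_len(slack, k)
  if (any(slack < 1)) stop("sim_scenario: slack must be >= 1")
  if (noise == "gaussian" && (is.null(gaussian_scale) || gaussian_scale <= 0))
    stop("sim_scenario: gaussian noise needs a positive 'gaussian_scale'")
  structure(list(n_ions = n_ions, mobility = mobility, center = center,
                 charge = as.integer(charge), cfg = cfg, noise = noise,
                 gaussian_scale = gaussian_scale, slack = slack,
                 dead_time = dead_time, background = background,
                 prior = prior),
            class = "sim_scenario")
}

# ground-truth components of a scenario at a given drift voltage
scenario_truth <- function(scn, drift_voltage = scn$cfg$drift_voltage) {
  cfg <- scn$cfg
  cfg$drift_voltage <- drift_voltage
  centers <- if (!is.null(scn$center)) scn$center else
    cfg$drift_length^2 / (scn$mobility * drift_voltage) + scn$dead_time
  o <- order(centers)
  n_ions <- scn$n_ions[o]; centers <- centers[o]; slack <- scn$slack[o]
  s2 <- slack^2 * sigma2_min(cfg, scn$charge, n_ions, centers)
  components(amplitude = n_ions / scn$prior$ions_per_count,
             center = centers, variance = s2)
}

default_grid <- function(truth, n = 200, span_sigma = 6) {
  sd_i <- sqrt(truth$variance)
  lo <- min(truth$center - span_sigma * sd_i)
  hi <- max(truth$center + span_sigma * sd_i)
  seq(lo, hi, length.out = n)
}

#' Simulate a single-voltage ATD
#'
#' Evaluates the mixture model of the scenario truth on the grid, converts
#' to expected counts per bin, and applies the scenario's noise model.
#'
#' @param scn A [sim_scenario()].
#' @param grid Uniform arrival-time grid (seconds). Default: 200 points
#'   covering all centers +/- 6 sigma. Must cover every center +/- 6 sigma.
#' @param seed Optional integer seed.
#' @return List with elements `atd` (an [atd()]), `truth` (the generating
#'   [components()]) and `scenario`.
#' @export
simulate_atd <- function(scn, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- scenario_truth(scn)
  if (is.null(grid)) grid <- default_grid(truth)
  sd_i <- sqrt(truth$variance)
  if (min(grid) > min(truth$center - 6 * sd_i) ||
      max(grid) < max(truth$center + 6 * sd_i))
    stop(sprintf(
      "simulate_atd: grid [%.4g, %.4g] ms does not cover all centers +/- 6 sigma ([%.4g, %.4g] ms)",
      1e3 * min(grid), 1e3 * max(grid),
      1e3 * min(truth$center - 6 * sd_i), 1e3 * max(truth$center + 6 * sd_i)))
  dt <- grid[2] - grid[1]
  lam <- mixture_model(grid, truth) * dt
  if (!is.null(scn$background)) {
    b <- scn$background
    lam <- lam + b$amplitude * stats::dnorm(grid, b$center, b$sd) * dt
  }
  x <- switch(scn$noise,
              poisson = stats::rpois(length(lam), lam),
              gaussian = pmax(0, lam + stats::rnorm(length(lam), 0, scn$gaussian_scale)),
              none = lam)
  list(atd = atd(grid, x, baseline_threshold = scn$prior$baseline_threshold),
       truth = truth, scenario = scn)
}

#' Simulate a stepped-field voltage series of ATDs
#'
#' Per-component centers follow the stepped-field law
#' t = L^2/(K V) + t0; variances are recomputed from the broadening physics
#' at each drift voltage.
#'
#' @param scn A [sim_scenario()] defined via mobilities.
#' @param voltages At least two distinct positive drift voltages.
#' @param grid Optional fixed grid; default regenerated per voltage.
#' @param seed Optional integer seed.
#' @return List (one element per voltage) of lists with `voltage`, `atd`,
#'   `truth`.
#' @export
simulate_voltage_series <- function(scn, voltages, grid = NULL, seed = NULL) {
  if (is.null(scn$mobility))
    stop("simulate_voltage_series: scenario must be defined via mobilities")
  if (length(unique(voltages)) < 2L)
    stop("simulate_voltage_series: need >= 2 distinct voltages")
  if (any(voltages <= 0))
    stop("simulate_voltage_series: voltages must be > 0")
  if (!is.null(seed)) set.seed(seed)
  lapply(voltages, function(v) {
    scn_v <- scn
    scn_v$cfg$drift_voltage <- v
    sim <- simulate_atd(scn_v, grid = grid, seed = NULL)
    list(voltage = v, atd = sim$atd, truth = sim$truth)
  })
}

#' Write a simulated ATD to CSV with a JSON ground-truth sidecar
#'
#' @param sim Result of [simulate_atd()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param time_unit Unit for the written arrival-time column.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  write_atd(sim$atd, path, time_unit = time_unit)
  side <- list(truth = as.data.frame(sim$truth),
               charge = sim$scenario$charge,
               noise = sim$scenario$noise,
               slack = sim$scenario$slack,
               instrument = unclass(sim$scenario$cfg))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
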