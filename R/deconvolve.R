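#' Control parameters for [deconvolve_atd()]
#'
#' @param steps_per_level Equi-energy steps per temperature level.
#' @param n_levels Temperature levels (geometric ladder, ratio sqrt(10)).
#' @param ee_jump_prob Equi-energy jump probability.
#' @param burn_in_fraction Burn-in fraction per chain stage.
#' @param bsp_max_leaves Leaves per BSP tree (default
#'   `2^ceiling(log2(sqrt(n)))`).
#' @param bsp_particles BSP importance-sampling particles.
#' @param rjmcmc_steps RJMCMC steps.
#' @param refresh_prob Within-dimension refresh probability in RJMCMC.
#' @param dim_prior `"flat"` or `"penalized"` prior over dimensions.
#' @param penalty_rate Geometric penalty rate when penalized.
#' @return List of class `"deconv_control"`.
#' @export
deconv_control <- function(steps_per_level = 2000, n_levels = 5,
                           ee_jump_prob = 0.1, burn_in_fraction = 0.2,
                           bsp_max_leaves = NULL, bsp_particles = 100,
                           rjmcmc_steps = 20000, refresh_prob = 0.5,
                           dim_prior = c("flat", "penalized"),
                           penalty_rate = 1) {
  structure(list(steps_per_level = as.integer(steps_per_level),
                 n_levels = as.integer(n_levels),
                 ee_jump_prob = ee_jump_prob,
                 burn_in_fraction = burn_in_fraction,
                 bsp_max_leaves = bsp_max_leaves,
                 bsp_particles = as.integer(bsp_particles),
                 rjmcmc_steps = as.integer(rjmcmc_steps),
                 refresh_prob = refresh_prob,
                 dim_prior = match.arg(dim_prior),
                 penalty_rate = penalty_rate),
            class = "deconv_control")
}

#' Deconvolve a multicomponent ATD with the three-stage Bayesian pipeline
#'
#' The central fitting function. For every candidate dimension k in
#' `k_range` the fixed-dimension posterior Pr(Theta_k | k, X) is sampled
#' with the equi-energy sampler; each sample set is discretized by
#' Bayesian sequential partitioning; the discretized posteriors drive a
#' reversible-jump MCMC whose visit frequencies give the posterior over
#' the number of components. The consensus solution is the
#' highest-posterior parameter vector of the modal dimension.
#'
#' @param atd An [atd()] object (or a two-column data.frame/matrix of
#'   arrival time in seconds and intensity).
#' @param k_range Integer range of candidate dimensions; width at most 4
#'   (the supervised `[k, k + 3]` window).
#' @param cfg An [instrument_config()].
#' @param prior A [prior_config()].
#' @param charge Ion charge state.
#' @param control A [deconv_control()].
#' @param seed Optional integer seed making the whole run reproducible.
#' @return Object of class `"atd_deconv"` with `dim_posterior`,
#'   `consensus` (modal k and its [components()]), `ee` (per-dimension
#'   sample sets), `trees` (per-dimension BSP partitions), and the inputs.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' scn <- sim_scenario(n_ions = c(6e4, 8e4), mobility = c(0.075, 0.060),
#'                     charge = 7L)
#' sim <- simulate_atd(scn, seed = 1)
#' fit <- deconvolve_atd(sim$atd, k_range = 1:3, charge = 7L, seed = 1,
#'                       control = deconv_control(steps_per_level = 400,
#'                                                bsp_particles = 20,
#'                                                rjmcmc_steps = 4000))
#' fit
#' }
#' @export
deconvolve_atd <- function(atd, k_range, cfg = instrument_config(),
                           prior = prior_config(), charge = 1L,
                           control = deconv_control(), seed = NULL) {
  cl <- match.call()
  if (!inherits(atd, "atd")) {
    atd <- as.data.frame(atd)
    atd <- atd(atd[[1]], atd[[2]],
               baseline_threshold = prior$baseline_threshold)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) - min(k_range) > 3L)
    stop("deconvolve_atd: k_range wider than the supervised [k, k+3] window")
  if (!all(diff(k_range) == 1L) && length(k_range) > 1L)
    stop("deconvolve_atd: k_range must be contiguous")
  if (!is.null(seed)) set.seed(seed)

  ladder <- ladder_config(n_levels = control$n_levels,
                          ee_jump_prob = control$ee_jump_prob,
                          steps_per_level = control$steps_per_level,
                          burn_in_fraction = control$burn_in_fraction)
  ee <- list(); trees <- list()
  w <- atd$window; a_max <- sum(atd$intensities)
  for (k in k_range) {
    es <- run_equi_energy(atd, k, ladder, cfg, prior, charge)
    ee[[as.character(k)]] <- es
    # clamp the proposal box at the hard constraints so independence
    # draws are not wasted on excluded states
    trees[[as.character(k)]] <- build_partition(
      es$samples, max_leaves = control$bsp_max_leaves,
      n_particles = control$bsp_particles,
      lower = c(rep(0, k), rep(w[1], k), rep(1, k)),
      upper = c(rep(a_max, k), rep(w[2], k), rep(Inf, k)))
  }
  dp <- if (length(k_range) == 1L) {
    k <- k_range
    structure(list(dims = k, probabilities = 1, mean_dimension = k,
                   map_theta_per_dim = stats::setNames(
                     list(ee[[as.character(k)]]$map), k),
                   visits = control$rjmcmc_steps,
                   n_steps = control$rjmcmc_steps,
                   acceptance = c(refresh = NA, jump = NA),
                   zero_density_rejects = 0L,
                   cfg = cfg, prior = prior, charge = charge),
              class = "dim_posterior")
  } else {
    run_rjmcmc(atd, trees, cfg, prior, charge,
               dim_prior = control$dim_prior,
               penalty_rate = control$penalty_rate,
               n_steps = control$rjmcmc_steps,
               refresh_prob = control$refresh_prob,
               burn_in_fraction = control$burn_in_fraction)
  }
  cons <- consensus_solution(dp, rule = "modal")[[1]]
  structure(list(atd = atd, k_range = k_range, dim_posterior = dp,
                 consensus = cons, ee = ee, trees = trees,
                 cfg = cfg, prior = prior, charge = charge,
                 control = control, seed = seed, call = cl),
            class = "atd_deconv")
}

#' @export
print.atd_deconv <- function(x, ...) {
  cat("Bayesian ATD deconvolution\n")
  cat(sprintf("  candidate dimensions %d-%d; modal k = %d (mean %.2f)\n",
              min(x$k_range), max(x$k_range), x$consensus$k,
              x$dim_posterior$mean_dimension))
  print(x$consensus$theta)
  invisible(x)
}

#' @export
coef.atd_deconv <- function(object, ...) {
  th <- object$consensus$theta
  cbind(amplitude = th$amplitude, center = th$center, variance = th$variance)
}

#' @export
fitted.atd_deconv <- function(object, ...) {
  mixture_model(object$atd$times, object$consensus$theta) * object$atd$dt
}

#' @export
residuals.atd_deconv <- function(object, ...) {
  object$atd$intensities - fitted(object)
}

#' Predict the fitted mixture on a time grid
#'
#' @param object An `"atd_deconv"` fit.
#' @param newdata Optional vector of arrival times (seconds); default the
#'   fitted grid.
#' @param type `"counts"` (per original grid bin) or `"density"`
#'   (counts per second).
#' @param per_component Return a matrix with one column per component plus
#'   a `total` column.
#' @param ... Unused.
#' @return Numeric vector, or matrix when `per_component = TRUE`.
#' @export
predict.atd_deconv <- function(object, newdata = NULL,
                               type = c("counts", "density"),
                               per_component = FALSE, ...) {
  type <- match.arg(type)
  tt <- if (is.null(newdata)) object$atd$times else as.numeric(newdata)
  th <- object$consensus$theta
  scale <- if (type == "counts") object$atd$dt else 1
  if (!per_component) return(mixture_model(tt, th) * scale)
  cols <- vapply(seq_len(th$k), function(i)
    th$amplitude[i] * stats::dnorm(tt, th$center[i], sqrt(th$variance[i])) * scale,
    numeric(length(tt)))
  cbind(cols, total = rowSums(cols))
}

#' @export
summary.atd_deconv <- function(object, ...) {
  th <- object$consensus$theta
  comp <- as.data.frame(th)
  comp$fraction <- population_fractions(th)
  r <- residuals(object)
  structure(list(dims = data.frame(k = object$dim_posterior$dims,
                                   probability = object$dim_posterior$probabilities),
                 mean_dimension = object$dim_posterior$mean_dimension,
                 modal_k = object$consensus$k, components = comp,
                 rmse = sqrt(mean(r^2)),
                 acceptance = object$dim_posterior$acceptance),
            class = "summary.atd_deconv")
}

#' @export
print.summary.atd_deconv <- function(x, ...) {
  cat("Bayesian ATD deconvolution\n\nDimension posterior:\n")
  print(x$dims, row.names = FALSE)
  cat(sprintf("mean dimension %.3f; modal k = %d\n\nComponents (modal k):\n",
              x$mean_dimension, x$modal_k))
  print(x$components, row.names = FALSE)
  cat(sprintf("\nresidual RMSE: %.4g counts per bin\n", x$rmse))
  invisible(x)
}

#' @export
plot.atd_deconv <- function(x, ...) {
  a <- x$atd
  graphics::plot(a$times * 1e3, a$intensities, type = "h", col = "grey70",
                 xlab = "arrival time (ms)", ylab = "counts per bin", ...)
  pc <- predict(x, per_component = TRUE)
  for (i in seq_len(ncol(pc) - 1L))
    graphics::lines(a$times * 1e3, pc[, i], col = "red3", lty = 2)
  graphics::lines(a$times * 1e3, pc[, "total"], col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate intensity replicates from a fitted deconvolution
#'
#' Draws Poisson counting-noise replicates of the fitted per-bin counts.
#'
#' @param object An `"atd_deconv"` fit.
#' @param nsim Number of replicate traces.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return `data.frame` with one column per replicate.
#' @export
simulate.atd_deconv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lam <- fitted(object)
  as.data.frame(matrix(stats::rpois(nsim * length(lam), lam),
                       ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Deconvolve a stepped-field voltage series and extract CCSs
#'
#' Runs [deconvolve_atd()] at each drift voltage, fixes the component
#' count by majority vote over the per-voltage modal dimensions (each
#' voltage's consensus parameters are then taken at that dimension, which
#' every voltage has sampled), links components across voltages, fits the
#' stepped-field linear relation and converts mobilities to CCSs.
#'
#' @param series List of `list(voltage=, atd=)` entries (e.g. from
#'   [simulate_voltage_series()]).
#' @param k_range Candidate dimension range (width at most 4).
#' @param cfg,prior,charge,control,seed As in [deconvolve_atd()];
#'   `cfg$drift_voltage` is overridden per series entry.
#' @param ion_mass Ion mass in u (for the Mason-Schamp conversion).
#' @return Object of class `"ccs_fit"`: `table` (the CCS results table),
#'   `fits` (per-voltage `"atd_deconv"`), `consensus_k`, `voltages`.
#' @export
deconvolve_series <- function(series, k_range, cfg = instrument_config(),
                              prior = prior_config(), charge = 1L,
                              control = deconv_control(), ion_mass,
                              seed = NULL) {
  if (length(series) < 3L)
    stop("deconvolve_series: need >= 3 voltages for stepped-field CCS")
  if (!is.null(seed)) set.seed(seed)
  voltages <- vapply(series, function(s) s$voltage, 0)
  fits <- lapply(series, function(s) {
    cfg_v <- cfg; cfg_v$drift_voltage <- s$voltage
    deconvolve_atd(s$atd, k_range, cfg_v, prior, charge, control)
  })
  modal <- vapply(fits, function(f) f$consensus$k, 0L)
  k_cons <- as.integer(names(which.max(table(modal))))
  thetas <- lapply(fits, function(f) {
    st <- f$dim_posterior$map_theta_per_dim[[as.character(k_cons)]]
    if (is.null(st)) st <- f$ee[[as.character(k_cons)]]$map
    state_to_components(st, k_cons, f$cfg, prior, charge)
  })
  tab <- ccs_table(thetas, voltages, cfg, charge, ion_mass)
  structure(list(table = tab, fits = fits, consensus_k = k_cons,
                 per_voltage_modal = modal, thetas = thetas,
                 voltages = voltages),
            class = "ccs_fit")
}

#' @export
print.ccs_fit <- function(x, ...) {
  cat(sprintf("Stepped-field CCS extraction: %d voltages, consensus k = %d\n",
              length(x$voltages), x$consensus_k))
  tab <- x$table
  tab$K <- signif(tab$K, 5); tab$K0 <- signif(tab$K0, 5)
  tab$CCS <- round(tab$CCS, 1); tab$CCS_error <- round(tab$CCS_error, 1)
  tab$R2 <- round(tab$R2, 4); tab$fraction <- round(tab$fraction, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
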