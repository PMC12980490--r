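# Physical constants (CODATA 2018), SI units.
.kB   <- 1.380649e-23      # Boltzmann constant, J K^-1
.e    <- 1.602176634e-19   # elementary charge, C
.eps0 <- 8.8541878128e-12  # vacuum permittivity, F m^-1
.amu  <- 1.66053906660e-27 # unified atomic mass unit, kg
.N0   <- 101325 / (.kB * 273.15) # Loschmidt number density, m^-3 (p0, T0)
.p0   <- 101325            # standard pressure, Pa
.T0   <- 273.15            # standard temperature, K

#' Instrument configuration for a drift-tube IMS experiment
#'
#' Bundles the geometric and operating parameters of a uniform-field drift
#' tube that enter the ion-cloud broadening model and the Mason-Schamp
#' conversion. All values are SI.
#'
#' The defaults describe a realistic low-pressure helium drift tube of
#' 0.2505 m length operated in the low-field regime; they are the
#' parametrization used throughout the package's synthetic validation.
#'
#' @param drift_length Drift region length L in metres.
#' @param drift_voltage Effective voltage gradient \eqn{\Delta V} across the
#'   drift region, in volts.
#' @param temperature Buffer gas temperature T in kelvin.
#' @param pressure Buffer gas pressure in pascal.
#' @param injection_pulse Duration of the (rectangular) injection pulse
#'   \eqn{t_{Inj}} in seconds.
#' @param buffer_gas_mass Buffer gas molecular mass in unified atomic mass
#'   units (default helium).
#' @param coulomb_factor Dimensionless proportionality factor
#'   \eqn{C_{Coul}} describing the charge distribution within the macro-ion.
#' @param number_density_ref Reference gas number density (molecules m^-3)
#'   used for reduced mobility; defaults to the Loschmidt constant.
#' @return An object of class `"instrument_config"` (a named list).
#' @examples
#' cfg <- instrument_config(drift_voltage = 120)
#' cfg$drift_length
#' @export
instrument_config <- function(drift_length = 0.2505,
                              drift_voltage = 150,
                              temperature = 298,
                              pressure = 400,
                              injection_pulse = 150e-6,
                              buffer_gas_mass = 4.002602,
                              coulomb_factor = 1.0,
                              number_density_ref = .N0) {
  cfg <- list(drift_length = drift_length,
              drift_voltage = drift_voltage,
              temperature = temperature,
              pressure = pressure,
              injection_pulse = injection_pulse,
              buffer_gas_mass = buffer_gas_mass,
              coulomb_factor = coulomb_factor,
              number_density_ref = number_density_ref)
  for (nm in setdiff(names(cfg), "coulomb_factor")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("instrument_config: '%s' must be a single positive finite number", nm))
  }
  if (cfg$coulomb_factor < 0)
    stop("instrument_config: 'coulomb_factor' must be >= 0")
  structure(cfg, class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("Drift-tube instrument configuration\n")
  cat(sprintf("  L = %.4f m, dV = %.4g V, T = %.4g K, p = %.4g Pa\n",
              x$drift_length, x$drift_voltage, x$temperature, x$pressure))
  cat(sprintf("  injection pulse = %.3g s, buffer gas = %.6g u, C_Coul = %.3g\n",
              x$injection_pulse, x$buffer_gas_mass, x$coulomb_factor))
  invisible(x)
}

#' Prior configuration for ATD deconvolution
#'
#' @param lambda_rate Rate \eqn{\lambda} of the shifted exponential prior on
#'   the variance multiplier \eqn{m = \sigma_t/\sigma_{min,t}}. Larger
#'   values keep widths closer to the physics-stated infimum. Default 35.
#' @param baseline_threshold Fraction of the maximum intensity below which a
#'   grid point counts as baseline; defines the sampling window (a, b).
#' @param ions_per_count Proportionality between the amplitude parameter
#'   \eqn{A_i} (observed counts) and the number of ions \eqn{N_i} entering
#'   the Coulomb term: \eqn{N_i = A_i \cdot} `ions_per_count`.
#' @return Object of class `"prior_config"`.
#' @export
prior_config <- function(lambda_rate = 35,
                         baseline_threshold = 0.01,
                         ions_per_count = 1.0) {
  if (lambda_rate <= 0) stop("prior_config: 'lambda_rate' must be > 0")
  if (baseline_threshold < 0 || baseline_threshold >= 1)
    stop("prior_config: 'baseline_threshold' must be in [0, 1)")
  if (ions_per_count <= 0) stop("prior_config: 'ions_per_count' must be > 0")
  structure(list(lambda_rate = lambda_rate,
                 baseline_threshold = baseline_threshold,
                 ions_per_count = ions_per_count),
            class = "prior_config")
}

#' Diffusion contribution to temporal ion-cloud variance
#'
#' Thermal diffusion broadening of an ion cloud after drift time t:
#' \deqn{\sigma^2_{Diff,t} = \frac{2 k_B T}{z e \Delta V} t^2}
#'
#' @param cfg An [instrument_config()].
#' @param charge Integer charge state z (>= 1).
#' @param arrival_time Drift/arrival time t in seconds (vectorized).
#' @return Variance in s^2.
#' @export
sigma2_diffusion <- function(cfg, charge, arrival_time) {
  if (any(charge < 1)) stop("sigma2_diffusion: charge must be >= 1")
  if (any(arrival_time < 0)) stop("sigma2_diffusion: arrival_time must be >= 0")
  2 * .kB * cfg$temperature / (charge * .e * cfg$drift_voltage) * arrival_time^2
}

#' Coulomb-repulsion contribution to temporal ion-cloud variance
#'
#' Space-charge broadening of a macro-ion of total charge Q = z e N:
#' \deqn{\sigma^2_{Coul,t} = C_{Coul}\left(\frac{3Q}{4\pi\epsilon_0 \Delta V L}\right)^{2/3} t^2}
#'
#' @inheritParams sigma2_diffusion
#' @param n_ions Number of ions N in the component (>= 0).
#' @return Variance in s^2.
#' @export
sigma2_coulomb <- function(cfg, charge, n_ions, arrival_time) {
  if (any(n_ions < 0)) stop("sigma2_coulomb: n_ions must be >= 0")
  Q <- charge * .e * n_ions
  cfg$coulomb_factor *
    (3 * Q / (4 * pi * .eps0 * cfg$drift_voltage * cfg$drift_length))^(2 / 3) *
    arrival_time^2
}

#' Injection contribution to temporal ion-cloud variance
#'
#' Variance of a rectangular injection pulse of duration \eqn{t_{Inj}}:
#' \eqn{t_{Inj}^2 / 12}.
#'
#' @inheritParams sigma2_diffusion
#' @return Variance in s^2.
#' @export
sigma2_injection <- function(cfg) {
  if (cfg$injection_pulse < 0) stop("sigma2_injection: injection pulse must be >= 0")
  cfg$injection_pulse^2 / 12
}

#' Minimum total temporal variance of an ion cloud
#'
#' Sum of injection, Coulomb and diffusion variances. This is the effective
#' infimum that any proposed component variance must respect; deviations
#' above it account for post-drift dispersion and background and are
#' governed by the exponential prior on m (see [prior_density_m()]).
#'
#' @inheritParams sigma2_coulomb
#' @return Variance in s^2.
#' @export
sigma2_min <- function(cfg, charge, n_ions, arrival_time) {
  sigma2_injection(cfg) +
    sigma2_coulomb(cfg, charge, n_ions, arrival_time) +
    sigma2_diffusion(cfg, charge, arrival_time)
}

#' Prior density of the variance multiplier m
#'
#' The component width is sampled as a multiple m = sigma_t / sigma_min,t of
#' the physics-stated infimum. Its prior is a shifted exponential:
#' 0 for m < 1, otherwise \eqn{\lambda e^{-\lambda (m - 1)}}.
#'
#' @param m Multiplier (vectorized).
#' @param prior A [prior_config()].
#' @return Density value(s).
#' @export
prior_density_m <- function(m, prior = prior_config()) {
  lam <- prior$lambda_rate
  ifelse(m < 1, 0, lam * exp(-lam * (m - 1)))
}

#' Gaussian mixture forward model for an ATD
#'
#' Evaluates \eqn{M(t,\Theta) = \sum_i \frac{A_i}{\sigma_i\sqrt{2\pi}}
#' e^{-(t-\mu_i)^2 / (2\sigma_i^2)}} elementwise. The output has units of
#' counts per second; multiplied by the grid step it gives expected counts
#' per bin.
#'
#' @param times Numeric vector of arrival times (seconds).
#' @param theta A [components()] object (amplitudes, centers, variances).
#' @return Numeric vector, same length as `times`.
#' @examples
#' th <- components(1000, 10e-3, (0.5e-3)^2)
#' mixture_model(10e-3, th)  # peak height A / (sigma sqrt(2 pi))
#' @export
mixture_model <- function(times, theta) {
  theta <- as_components(theta)
  if (any(!is.finite(times))) stop("mixture_model: times must be finite")
  out <- numeric(length(times))
  sd_i <- sqrt(theta$variance)
  for (i in seq_along(theta$amplitude)) {
    out <- out + theta$amplitude[i] * stats::dnorm(times, theta$center[i], sd_i[i])
  }
  out
}

# Robust single noise scale for the Gaussian-error energy. Baseline MAD,
# floored at sqrt(max intensity): a clean synthetic ATD has an all-zero
# baseline (MAD 0) while counting noise at the peak scales as sqrt(counts).
noise_scale <- function(atd, prior = prior_config()) {
  x <- atd$intensities
  base <- x[x < prior$baseline_threshold * max(x)]
  s_mad <- if (length(base) >= 5) stats::mad(base, center = 0) else 0
  max(s_mad, sqrt(max(x)), .Machine$double.eps)
}

#' Unnormalized log posterior of a component set given an ATD
#'
#' Combines the Gaussian-noise likelihood of the mixture model with the
#' uniform priors on centers (within the sampling window) and amplitudes
#' (in `[0, total counts]`), and the shifted-exponential prior on the
#' variance multiplier m of each component. Returns `-Inf` when any hard
#' constraint is violated: a center outside the window (a, b), a negative
#' amplitude, or a variance below the physics infimum of
#' [sigma2_min()] evaluated at that component's center and ion count.
#'
#' The sampler energy is the negative of this value.
#'
#' @param theta A [components()] object.
#' @param atd An [atd()] object.
#' @param cfg An [instrument_config()].
#' @param prior A [prior_config()].
#' @param charge Integer charge state of the ion.
#' @return A single finite number, or `-Inf` for excluded parameter sets.
#' @export
log_posterior <- function(theta, atd, cfg, prior = prior_config(), charge = 1L) {
  theta <- as_components(theta)
  m <- multiplier_of(theta, cfg, prior, charge)
  if (anyNA(m)) return(-Inf)
  st <- c(theta$amplitude, theta$center, m)
  .log_post_state(st, length(theta$amplitude), atd, cfg, prior, charge)
}

# m_i = sigma_i / sigma_min_i for explicit-variance components; NA where the
# hard constraints fail.
multiplier_of <- function(theta, cfg, prior, charge) {
  n_ions <- theta$amplitude * prior$ions_per_count
  s2min <- sigma2_min(cfg, charge, n_ions, theta$center)
  m <- sqrt(theta$variance / s2min)
  m[theta$variance < s2min * (1 - 1e-12)] <- NA_real_
  m
}

# Internal fast path: state vector st = c(A[1:k], mu[1:k], m[1:k]).
# The (A, mu, m) coordinates are the sampling space used by every sampler;
# sigma_i^2 = m_i^2 * sigma2_min(mu_i, N_i) is derived.
.log_post_state <- function(st, k, atd, cfg, prior, charge,
                            s = noise_scale(atd, prior)) {
  A  <- st[seq_len(k)]
  mu <- st[k + seq_len(k)]
  m  <- st[2L * k + seq_len(k)]
  w <- atd$window
  a_max <- sum(atd$intensities)
  if (any(A < 0) || any(A > a_max) || any(mu <= w[1]) || any(mu >= w[2]) ||
      any(m < 1) || any(!is.finite(st)))
    return(-Inf)
  n_ions <- A * prior$ions_per_count
  s2 <- m^2 * sigma2_min(cfg, charge, n_ions, mu)
  model <- .mixture_counts(atd$times, A, mu, sqrt(s2)) * atd$dt
  r <- atd$intensities - model
  lam <- prior$lambda_rate
  -sum(r * r) / (2 * s * s) +
    k * (log(lam) - log(w[2] - w[1]) - log(a_max)) - lam * sum(m - 1)
}

# mixture density without constructor overhead
.mixture_counts <- function(times, A, mu, sd_i) {
  out <- numeric(length(times))
  for (i in seq_along(A)) out <- out + A[i] * stats::dnorm(times, mu[i], sd_i[i])
  out
}
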