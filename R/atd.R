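#' Construct an arrival time distribution (ATD)
#'
#' An ATD is an intensity (ion count per bin) trace on a strictly
#' increasing, uniform arrival-time grid. The sampling window (a, b) is the
#' smallest interval bracketing every grid point whose intensity exceeds
#' `baseline_threshold` times the maximum; components may only be placed
#' inside it.
#'
#' @param times Arrival times, strictly increasing uniform grid.
#' @param intensities Nonnegative counts, same length as `times`.
#' @param time_unit `"s"` (default) or `"ms"`; times are stored in seconds.
#' @param baseline_threshold Fraction of the maximum intensity defining the
#'   window.
#' @return Object of class `"atd"`: list with `times`, `intensities`,
#'   `window` (a, b in seconds) and `dt` (grid step).
#' @examples
#' t <- seq(4, 9, length.out = 200) * 1e-3
#' x <- 1e4 * dnorm(t, 6e-3, 0.3e-3) * diff(t)[1]
#' a <- atd(t, x)
#' a$window
#' @export
atd <- function(times, intensities, time_unit = c("s", "ms"),
                baseline_threshold = 0.01) {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (time_unit == "ms") times <- times * 1e-3
  if (length(times) != length(intensities))
    stop("atd: times and intensities must have equal length")
  if (length(times) < 5L) stop("atd: need at least 5 grid points")
  dt <- diff(times)
  if (any(dt <= 0)) stop("atd: times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("atd: times must form a uniform grid")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("atd: intensities must be finite and nonnegative")
  if (all(intensities == 0)) stop("atd: all intensities are zero")
  obj <- list(times = times, intensities = intensities,
              dt = stats::median(dt),
              baseline_threshold = baseline_threshold)
  obj$window <- atd_window(obj, baseline_threshold)
  structure(obj, class = "atd")
}

#' Sampling window of an ATD
#'
#' Returns (a, b): the time span bracketing all grid points with intensity
#' above `threshold` of the maximum, widened by half a grid step on each
#' side so that above-threshold points are strictly interior.
#'
#' @param x An [atd()] object.
#' @param threshold Fraction of the maximum intensity.
#' @return Numeric length-2 vector (a, b), seconds.
#' @export
atd_window <- function(x, threshold = x$baseline_threshold) {
  keep <- which(x$intensities > threshold * max(x$intensities))
  c(x$times[min(keep)] - x$dt / 2, x$times[max(keep)] + x$dt / 2)
}

#' @export
print.atd <- function(x, ...) {
  cat(sprintf("ATD: %d points, %.4g - %.4g ms (dt = %.4g ms)\n",
              length(x$times), 1e3 * min(x$times), 1e3 * max(x$times),
              1e3 * x$dt))
  cat(sprintf("  window (a, b) = (%.4g, %.4g) ms; total counts = %.4g\n",
              1e3 * x$window[1], 1e3 * x$window[2], sum(x$intensities)))
  invisible(x)
}

#' @export
plot.atd <- function(x, ...) {
  graphics::plot(x$times * 1e3, x$intensities, type = "h", col = "grey40",
                 xlab = "arrival time (ms)", ylab = "counts per bin", ...)
  graphics::abline(v = x$window * 1e3, lty = 3, col = "red3")
  invisible(x)
}

#' Construct a set of Gaussian ATD components
#'
#' A component set (parameter vector) holds the amplitudes (ion counts),
#' centers (mean arrival times, seconds) and variances (s^2) of k Gaussian
#' components, stored sorted by center (identifiability convention).
#'
#' @param amplitude Nonnegative amplitudes.
#' @param center Mean arrival times in seconds.
#' @param variance Strictly positive variances in s^2.
#' @return Object of class `"atd_components"`.
#' @export
components <- function(amplitude, center, variance) {
  k <- length(center)
  if (length(amplitude) != k || length(variance) != k)
    stop("components: amplitude, center, variance must have equal length")
  if (k < 1L) stop("components: need at least one component")
  if (any(amplitude < 0)) stop("components: amplitudes must be >= 0")
  if (any(variance <= 0)) stop("components: variances must be > 0")
  o <- order(center)
  structure(list(amplitude = as.numeric(amplitude)[o],
                 center = as.numeric(center)[o],
                 variance = as.numeric(variance)[o], k = k),
            class = "atd_components")
}

as_components <- function(x) {
  if (inherits(x, "atd_components")) return(x)
  if (is.list(x) && all(c("amplitude", "center", "variance") %in% names(x)))
    return(components(x$amplitude, x$center, x$variance))
  stop("expected an 'atd_components' object")
}

#' @export
print.atd_components <- function(x, ...) {
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.atd_components <- function(x, ...) {
  data.frame(component = seq_len(x$k), amplitude = x$amplitude,
             center_ms = x$center * 1e3, sigma_ms = sqrt(x$variance) * 1e3)
}

# state vector c(A, mu, m) <-> components, given physics context
state_to_components <- function(st, k, cfg, prior, charge) {
  A <- st[seq_len(k)]; mu <- st[k + seq_len(k)]; m <- st[2L * k + seq_len(k)]
  s2 <- m^2 * sigma2_min(cfg, charge, A * prior$ions_per_count, mu)
  components(A, mu, s2)
}

components_to_state <- function(theta, cfg, prior, charge) {
  theta <- as_components(theta)
  m <- multiplier_of(theta, cfg, prior, charge)
  c(theta$amplitude, theta$center, m)
}

#' Per-component population fractions
#'
#' @param theta A [components()] object.
#' @return Simplex of amplitude fractions \eqn{A_i / \sum_j A_j}.
#' @export
population_fractions <- function(theta) {
  theta <- as_components(theta)
  tot <- sum(theta$amplitude)
  if (tot <= 0) stop("population_fractions: total amplitude must be > 0")
  theta$amplitude / tot
}
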