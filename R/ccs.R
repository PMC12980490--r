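# Stepped-field mobility extraction and Mason-Schamp CCS conversion.
# In a uniform low-field drift tube the arrival time is linear in the
# inverse drift voltage, t = L^2/(K V) + t0, so an ordinary least squares
# fit of t against 1/V yields the mobility from the slope; a strongly
# nonlinear trend flags an incorrect deconvolution.

#' Fit the stepped-field linear relation for one component
#'
#' Ordinary least squares of arrival time against inverse drift voltage.
#' The slope equals L^2/K, giving the mobility K; the intercept is the
#' field-free dead time t0. The mobility confidence interval is propagated
#' from the slope standard error (3 sigma by default).
#'
#' @param centers Arrival times (seconds), one per voltage.
#' @param voltages Drift voltages (V), at least 3 distinct values.
#' @param cfg An [instrument_config()] (drift length).
#' @param conf_sigma Width of the reported confidence interval in standard
#'   errors (default 3).
#' @param r2_flag R^2 below which the fit is flagged as nonlinear
#'   (an incorrect deconvolution indicator).
#' @return List with `K` (m^2 V^-1 s^-1), `K_err`, `t0`, `r_squared`,
#'   `slope`, `slope_se`, `nonlinear_flag`.
#' @export
fit_stepped_field <- function(centers, voltages, cfg = instrument_config(),
                              conf_sigma = 3, r2_flag = 0.99) {
  if (length(centers) != length(voltages))
    stop("fit_stepped_field: centers and voltages must have equal length")
  if (length(unique(voltages)) < 3L)
    stop("fit_stepped_field: need >= 3 distinct voltages")
  if (any(voltages <= 0)) stop("fit_stepped_field: voltages must be > 0")
  inv_v <- 1 / voltages
  fit <- stats::lm(centers ~ inv_v)
  slope <- unname(stats::coef(fit)[2])
  t0 <- unname(stats::coef(fit)[1])
  if (slope <= 0)
    stop("fit_stepped_field: nonpositive slope (nonphysical mobility) - bad deconvolution")
  r2 <- summary(fit)$r.squared
  slope_se <- summary(fit)$coefficients[2, 2]
  K <- cfg$drift_length^2 / slope
  K_err <- conf_sigma * slope_se * cfg$drift_length^2 / slope^2
  list(K = K, K_err = K_err, t0 = t0, r_squared = r2,
       slope = slope, slope_se = slope_se,
       nonlinear_flag = r2 < r2_flag)
}

# reduced mass of ion and buffer gas, kg
.reduced_mass <- function(ion_mass_u, gas_mass_u) {
  (ion_mass_u * gas_mass_u) / (ion_mass_u + gas_mass_u) * .amu
}

#' Convert a mobility to a collision cross section (Mason-Schamp)
#'
#' \deqn{\Omega = \frac{3 z e}{16 N} \sqrt{\frac{2\pi}{\mu k_B T}} \frac{1}{K}}
#' with N the buffer gas number density at the measurement conditions and
#' \eqn{\mu} the ion/buffer-gas reduced mass. Also reports the reduced
#' mobility K0 = K (p/p0)(T0/T).
#'
#' @param K Mobility in m^2 V^-1 s^-1.
#' @param cfg An [instrument_config()] (temperature, pressure, buffer gas).
#' @param charge Ion charge state z.
#' @param ion_mass Ion mass in unified atomic mass units.
#' @return List with `ccs` (in Angstrom^2), `K0` (m^2 V^-1 s^-1).
#' @export
mobility_to_ccs <- function(K, cfg = instrument_config(), charge = 1L,
                            ion_mass) {
  if (any(K <= 0)) stop("mobility_to_ccs: K must be > 0")
  if (ion_mass <= 0 || cfg$buffer_gas_mass <= 0)
    stop("mobility_to_ccs: masses must be > 0")
  mu <- .reduced_mass(ion_mass, cfg$buffer_gas_mass)
  N <- cfg$pressure / (.kB * cfg$temperature)
  ccs_m2 <- 3 * charge * .e / (16 * N) *
    sqrt(2 * pi / (mu * .kB * cfg$temperature)) / K
  list(ccs = ccs_m2 * 1e20,
       K0 = K * (cfg$pressure / .p0) * (.T0 / cfg$temperature))
}

#' Inverse of [mobility_to_ccs()]
#'
#' @param ccs Collision cross section in Angstrom^2.
#' @inheritParams mobility_to_ccs
#' @return Mobility K in m^2 V^-1 s^-1.
#' @export
ccs_to_mobility <- function(ccs, cfg = instrument_config(), charge = 1L,
                            ion_mass) {
  if (any(ccs <= 0)) stop("ccs_to_mobility: ccs must be > 0")
  mu <- .reduced_mass(ion_mass, cfg$buffer_gas_mass)
  N <- cfg$pressure / (.kB * cfg$temperature)
  3 * charge * .e / (16 * N) *
    sqrt(2 * pi / (mu * .kB * cfg$temperature)) / (ccs * 1e-20)
}

#' Link components across a voltage series
#'
#' With a constant component count per voltage, `"mobility_consistent"`
#' links components by their center rank at each voltage (valid because
#' arrival time is monotone in 1/K at fixed voltage), giving a bijection
#' per adjacent voltage pair. `"nearest_center"` greedily matches nearest
#' centers between adjacent voltages.
#'
#' @param per_voltage_thetas List of [components()] objects, one per
#'   voltage (equal dimension required).
#' @param mode Linking mode.
#' @return Integer matrix (components x voltages): entry `[i, v]` is the
#'   index within voltage `v`'s component set belonging to linked
#'   component `i`.
#' @export
link_components <- function(per_voltage_thetas,
                            mode = c("mobility_consistent", "nearest_center")) {
  mode <- match.arg(mode)
  ks <- vapply(per_voltage_thetas, function(t) as_components(t)$k, 0L)
  if (length(unique(ks)) != 1L)
    stop(sprintf("link_components: unequal dimensions across voltages: %s",
                 paste(ks, collapse = ", ")))
  k <- ks[1]; nv <- length(per_voltage_thetas)
  links <- matrix(0L, k, nv)
  if (mode == "mobility_consistent") {
    # components() stores center-sorted, so rank i = index i at each voltage
    links[] <- rep(seq_len(k), nv)
  } else {
    links[, 1] <- seq_len(k)
    for (v in 2:nv) {
      prev <- as_components(per_voltage_thetas[[v - 1L]])$center[links[, v - 1L]]
      cur <- as_components(per_voltage_thetas[[v]])$center
      remaining <- seq_len(k)
      for (i in order(vapply(prev, function(p) min(abs(p - cur)), 0))) {
        j <- remaining[which.min(abs(cur[remaining] - prev[i]))]
        links[i, v] <- j
        remaining <- setdiff(remaining, j)
      }
    }
  }
  links
}

#' Stepped-field CCS extraction from per-voltage component sets
#'
#' Links components across voltages, fits the linear arrival time vs
#' inverse voltage relation per component, and converts each mobility to a
#' CCS. This mirrors the standard results table: component, K, K0, CCS,
#' CCS error (from the slope covariance, 3 sigma), R^2 and population
#' fraction.
#'
#' @param per_voltage_thetas List of [components()] (equal dimension).
#' @param voltages Drift voltages, same length.
#' @param cfg An [instrument_config()].
#' @param charge Ion charge state.
#' @param ion_mass Ion mass in u.
#' @param conf_sigma Confidence width in sigma for the CCS error.
#' @return `data.frame` with columns `component`, `K`, `K0`, `CCS`,
#'   `CCS_error`, `R2`, `fraction`.
#' @export
ccs_table <- function(per_voltage_thetas, voltages,
                      cfg = instrument_config(), charge = 1L, ion_mass,
                      conf_sigma = 3) {
  links <- link_components(per_voltage_thetas)
  k <- nrow(links)
  fr <- rowMeans(vapply(per_voltage_thetas,
                        function(t) population_fractions(t), numeric(k)))
  rows <- lapply(seq_len(k), function(i) {
    centers <- vapply(seq_along(voltages), function(v)
      as_components(per_voltage_thetas[[v]])$center[links[i, v]], 0)
    sf <- fit_stepped_field(centers, voltages, cfg, conf_sigma = conf_sigma)
    ms <- mobility_to_ccs(sf$K, cfg, charge, ion_mass)
    # CCS is proportional to 1/K, i.e. to the slope: relative errors match
    data.frame(component = i, K = sf$K, K0 = ms$K0, CCS = ms$ccs,
               CCS_error = ms$ccs * conf_sigma * sf$slope_se / sf$slope,
               R2 = sf$r_squared, fraction = fr[i])
  })
  do.call(rbind, rows)
}

#' Flag likely background components
#'
#' Broad, low-amplitude components sitting between the main peaks are
#' usually contaminating ion background rather than conformations. A
#' component is flagged when its width exceeds `width_factor` times the
#' physics-infimum width at its own center/ion count and its amplitude is
#' below `amp_frac` of the largest amplitude.
#'
#' @param theta A [components()] object.
#' @param cfg,prior,charge Physics context.
#' @param width_factor Width multiple of the infimum (default 3).
#' @param amp_frac Amplitude fraction of the maximum (default 0.1).
#' @return Logical vector, `TRUE` for flagged components.
#' @export
flag_background <- function(theta, cfg = instrument_config(),
                            prior = prior_config(), charge = 1L,
                            width_factor = 3, amp_frac = 0.1) {
  theta <- as_components(theta)
  s2min <- sigma2_min(cfg, charge, theta$amplitude * prior$ions_per_count,
                      theta$center)
  sqrt(theta$variance) > width_factor * sqrt(s2min) &
    theta$amplitude < amp_frac * max(theta$amplitude)
}

#' Track components across a collision-voltage (CIU) series
#'
#' Greedy nearest-center matching between adjacent collision voltages
#' within a tolerance. Components without a match at the next voltage end
#' their track (a disappearing conformer family); unmatched components at
#' the next voltage start a new track. Per-step dimension changes and
#' center shifts are reported.
#'
#' @param results List ordered by collision voltage; each element a
#'   `list(voltage=, theta=)` with `theta` a [components()] object.
#' @param tolerance Maximum center shift (seconds) for two components at
#'   adjacent voltages to be considered the same family.
#' @return Object of class `"ciu_track"`: `tracks` (data.frame with
#'   `track`, `voltage`, `center`, `amplitude`), `dimension`
#'   (per-voltage component count), `shifts` (data.frame of per-step
#'   matched center shifts), `collision_voltages`.
#' @export
track_ciu <- function(results, tolerance = 0.5e-3) {
  nv <- length(results)
  if (nv == 0L)
    return(structure(list(tracks = data.frame(), dimension = integer(),
                          shifts = data.frame(), collision_voltages = numeric()),
                     class = "ciu_track"))
  voltages <- vapply(results, function(r) r$voltage, 0)
  if (is.unsorted(voltages)) stop("track_ciu: results must be ordered by collision voltage")
  thetas <- lapply(results, function(r) as_components(r$theta))
  dims <- vapply(thetas, function(t) t$k, 0L)

  track_id <- list(seq_len(dims[1]))     # per voltage: track id of each component
  next_id <- dims[1] + 1L
  shifts <- list()
  if (nv > 1) for (v in 2:nv) {
    prev <- thetas[[v - 1L]]$center; cur <- thetas[[v]]$center
    ids <- integer(length(cur))
    un_prev <- seq_along(prev); un_cur <- seq_along(cur)
    # greedy: repeatedly match the globally closest remaining pair in tolerance
    repeat {
      if (!length(un_prev) || !length(un_cur)) break
      dmat <- abs(outer(prev[un_prev], cur[un_cur], "-"))
      if (min(dmat) > tolerance) break
      w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      pi <- un_prev[w[1]]; ci <- un_cur[w[2]]
      ids[ci] <- track_id[[v - 1L]][pi]
      shifts[[length(shifts) + 1L]] <-
        data.frame(from_voltage = voltages[v - 1L], to_voltage = voltages[v],
                   track = ids[ci], shift = cur[ci] - prev[pi])
      un_prev <- setdiff(un_prev, pi); un_cur <- setdiff(un_cur, ci)
    }
    for (ci in un_cur) { ids[ci] <- next_id; next_id <- next_id + 1L }
    track_id[[v]] <- ids
  }
  tracks <- do.call(rbind, lapply(seq_len(nv), function(v)
    data.frame(track = track_id[[v]], voltage = voltages[v],
               center = thetas[[v]]$center, amplitude = thetas[[v]]$amplitude)))
  structure(list(tracks = tracks[order(tracks$track, tracks$voltage), ],
                 dimension = dims,
                 shifts = if (length(shifts)) do.call(rbind, shifts)
                          else data.frame(),
                 collision_voltages = voltages),
            class = "ciu_track")
}

#' @export
print.ciu_track <- function(x, ...) {
  cat(sprintf("CIU track over %d collision voltages; dimensions: %s\n",
              length(x$collision_voltages),
              paste(x$dimension, collapse = " ")))
  n_tracks <- length(unique(x$tracks$track))
  cat(sprintf("  %d tracks; %d matched transitions\n", n_tracks,
              nrow(x$shifts)))
  invisible(x)
}
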