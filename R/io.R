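#' Read an ATD from a two-column text file
#'
#' Accepts comma-, tab- or whitespace-delimited files (delimiter
#' auto-detected) of arrival time and intensity, with an optional header
#' line. Negative intensities are clipped to zero with a warning.
#'
#' @param path File path.
#' @param time_unit Unit of the time column: `"ms"` (the common export
#'   convention, default) or `"s"`.
#' @param baseline_threshold Passed to [atd()].
#' @return An [atd()] object.
#' @export
read_atd <- function(path, time_unit = c("ms", "s"),
                     baseline_threshold = 0.01) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop(sprintf("read_atd: no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 5L)
    stop(sprintf("read_atd: %s: need at least 5 data rows", path))
  sep <- if (grepl(",", lines[min(2, length(lines))])) "," else ""
  first_numeric <- !anyNA(suppressWarnings(
    as.numeric(strsplit(trimws(lines[1]), if (sep == ",") "," else "[ \t]+")[[1]])))
  df <- utils::read.table(text = lines, sep = sep, header = !first_numeric,
                          strip.white = TRUE)
  if (ncol(df) < 2L)
    stop(sprintf("read_atd: %s: expected two numeric columns (time, intensity), found %d column(s)",
                 path, ncol(df)))
  tt <- suppressWarnings(as.numeric(df[[1]]))
  xx <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(!is.finite(tt) | !is.finite(xx))
  if (length(bad))
    stop(sprintf("read_atd: %s: non-numeric cells at data line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  if (is.unsorted(tt, strictly = TRUE))
    stop(sprintf("read_atd: %s: times must be strictly increasing (first violation at data line %d)",
                 path, which(diff(tt) <= 0)[1] + 1L))
  n_neg <- sum(xx < 0)
  if (n_neg) {
    warning(sprintf("read_atd: %s: clipped %d negative intensities to 0", path, n_neg))
    xx[xx < 0] <- 0
  }
  atd(tt, xx, time_unit = time_unit, baseline_threshold = baseline_threshold)
}

#' Write an ATD to a two-column CSV
#'
#' @param x An [atd()] object.
#' @param path Output path.
#' @param time_unit Unit for the written time column.
#' @return `path`, invisibly.
#' @export
write_atd <- function(x, path, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  tt <- if (time_unit == "ms") x$times * 1e3 else x$times
  df <- data.frame(arrival_time = tt, intensity = x$intensities)
  names(df)[1] <- sprintf("arrival_time_%s", time_unit)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# permitted keys per run-config block; unknown keys are hard errors
.config_schema <- list(
  instrument = c("drift_length", "drift_voltage", "temperature", "pressure",
                 "injection_pulse", "buffer_gas_mass", "coulomb_factor",
                 "number_density_ref"),
  prior = c("lambda_rate", "baseline_threshold", "ions_per_count"),
  ladder = c("n_levels", "temperatures", "energy_cutoffs", "ee_jump_prob",
             "steps_per_level", "burn_in_fraction"),
  bsp = c("max_leaves", "n_particles"),
  rjmcmc = c("k_min", "k_max", "n_steps", "dim_prior", "penalty_rate",
             "refresh_prob"),
  top = c("instrument", "prior", "ladder", "bsp", "rjmcmc", "charge",
          "ion_mass", "seed", "output_dir", "time_unit"))

#' Read and validate a JSON run configuration
#'
#' The configuration is a JSON object with optional blocks `instrument`,
#' `prior`, `ladder`, `bsp` and `rjmcmc`, plus top-level `charge`,
#' `ion_mass`, `seed`, `output_dir` and `time_unit`. Unknown keys are
#' errors (no silent typos); the `[k, k+3]` dimension-window rule is
#' enforced. Missing values take the package defaults, and the fully
#' resolved configuration is returned.
#'
#' @param path JSON file path.
#' @return Named list with materialized defaults: `cfg`
#'   ([instrument_config()]), `prior` ([prior_config()]), `control`
#'   ([deconv_control()]), `k_range`, `charge`, `ion_mass`, `seed`,
#'   `output_dir`, `time_unit`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  chk <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop(sprintf("read_run_config: unknown key(s) in %s: %s",
                   where, paste(extra, collapse = ", ")))
  }
  chk(raw, .config_schema$top, "top level")
  for (b in c("instrument", "prior", "ladder", "bsp", "rjmcmc"))
    if (!is.null(raw[[b]])) chk(raw[[b]], .config_schema[[b]], b)
  cfg <- do.call(instrument_config, as.list(raw$instrument))
  prior <- do.call(prior_config, as.list(raw$prior))
  rj <- as.list(raw$rjmcmc)
  k_min <- rj$k_min %||% 1L; k_max <- rj$k_max %||% (k_min + 3L)
  if (k_max - k_min > 3L)
    stop(sprintf("read_run_config: k_max - k_min = %d violates the supervised [k, k+3] window",
                 k_max - k_min))
  ladder <- as.list(raw$ladder); bsp <- as.list(raw$bsp)
  control <- deconv_control(
    steps_per_level = ladder$steps_per_level %||% 1500,
    n_levels = ladder$n_levels %||% 5,
    ee_jump_prob = ladder$ee_jump_prob %||% 0.1,
    burn_in_fraction = ladder$burn_in_fraction %||% 0.2,
    bsp_max_leaves = bsp$max_leaves,
    bsp_particles = bsp$n_particles %||% 100,
    rjmcmc_steps = rj$n_steps %||% 20000,
    refresh_prob = rj$refresh_prob %||% 0.5,
    dim_prior = rj$dim_prior %||% "flat",
    penalty_rate = rj$penalty_rate %||% 1)
  list(cfg = cfg, prior = prior, control = control,
       k_range = seq.int(k_min, k_max),
       charge = as.integer(raw$charge %||% 1L),
       ion_mass = raw$ion_mass,
       seed = raw$seed,
       output_dir = raw$output_dir %||% ".",
       time_unit = raw$time_unit %||% "ms")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON deconvolution report
#'
#' Emits the dimension posterior, per-dimension MAP parameters,
#' acceptance rates, consensus components, the seed and the resolved
#' configuration, so a run can be audited and reproduced bit-identically.
#'
#' @param fit An `"atd_deconv"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  dp <- fit$dim_posterior
  report <- list(
    dimension_posterior = list(dims = dp$dims,
                               probabilities = dp$probabilities,
                               mean_dimension = dp$mean_dimension),
    consensus = list(k = fit$consensus$k,
                     components = as.data.frame(fit$consensus$theta),
                     fractions = population_fractions(fit$consensus$theta)),
    map_per_dimension = lapply(dp$map_theta_per_dim, function(s)
      if (is.null(s)) NULL else unname(s)),
    acceptance = as.list(dp$acceptance),
    zero_density_rejects = dp$zero_density_rejects,
    seed = fit$seed,
    config = list(instrument = unclass(fit$cfg),
                  prior = unclass(fit$prior),
                  control = unclass(fit$control),
                  charge = fit$charge,
                  k_range = fit$k_range))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-dimension posterior samples to CSV
#'
#' One row per equi-energy sample: the dimension, the parameter columns
#' `A1..Ak, mu1..muk, m1..mk` and the energy.
#'
#' @param fit An `"atd_deconv"` object.
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_sample_dump <- function(fit, dir = ".") {
  paths <- vapply(fit$ee, function(es) {
    df <- cbind(k = es$dimension, as.data.frame(es$samples),
                energy = es$energies)
    p <- file.path(dir, sprintf("samples_k%d.csv", es$dimension))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read a stepped-field manifest
#'
#' A manifest is a CSV with columns `path` and `voltage` (plus optional
#' `pressure`, `temperature` overrides) listing one ATD file per drift
#' voltage.
#'
#' @param path Manifest CSV path.
#' @param time_unit Unit of the ATD time columns.
#' @param baseline_threshold Passed to [read_atd()].
#' @return List of `list(voltage=, atd=)` suitable for
#'   [deconvolve_series()].
#' @export
read_manifest <- function(path, time_unit = "ms", baseline_threshold = 0.01) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "voltage") %in% names(man)))
    stop("read_manifest: manifest needs 'path' and 'voltage' columns")
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("read_manifest: row %d (voltage %g): file not found: %s",
                   i, man$voltage[i], man$path[i]))
    list(voltage = man$voltage[i],
         atd = read_atd(p, time_unit = time_unit,
                        baseline_threshold = baseline_threshold))
  })
}
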