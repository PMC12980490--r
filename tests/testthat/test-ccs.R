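test_that("stepped-field fit recovers exact mobilities from noiseless data", {
  cfg <- instrument_config()
  volts <- c(100, 120, 140, 160, 180, 200)
  K_true <- 1e-3
  centers <- cfg$drift_length^2 / (K_true * volts)
  suppressWarnings(fit <- fit_stepped_field(centers, volts, cfg))
  expect_equal(fit$K, K_true, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(abs(fit$t0), 1e-12)
  expect_false(fit$nonlinear_flag)
  # a nonzero dead time lands in the intercept, not the slope
  suppressWarnings(fit2 <- fit_stepped_field(centers + 2e-4, volts, cfg))
  expect_equal(fit2$K, K_true, tolerance = 1e-10)
  expect_equal(fit2$t0, 2e-4, tolerance = 1e-8)
})

test_that("stepped-field fit is accurate and unbiased under center noise", {
  cfg <- instrument_config()
  volts <- c(100, 120, 140, 160, 180, 200)
  K_true <- 8e-4
  centers <- cfg$drift_length^2 / (K_true * volts)
  set.seed(71)
  out <- replicate(200, {
    noisy <- centers * (1 + stats::rnorm(6, 0, 1e-3))
    fit <- fit_stepped_field(noisy, volts, cfg)
    c(fit$K / K_true - 1, fit$r_squared)
  })
  rel_err <- out[1, ]
  # per-seed error sd is ~0.17%, so 0.5% is a ~3 sigma band: nearly all
  # seeds inside, and the estimator unbiased well below 0.1%
  expect_gt(mean(abs(rel_err) < 0.005), 0.95)
  expect_lt(max(abs(rel_err)), 0.01)
  expect_lt(abs(mean(rel_err)), 0.001)
  expect_gt(mean(out[2, ]), 0.999)
})

test_that("nonlinear arrival-time trends are flagged as bad deconvolutions", {
  cfg <- instrument_config()
  volts <- c(100, 120, 140, 160, 180, 200)
  # strongly curved fake centers (cubic in 1/V; a pure quadratic on this
  # narrow 1/V design still yields R^2 = 0.991 and needs the configurable
  # threshold raised to be caught)
  curved <- 2e5 * (1 / volts)^3
  fit <- fit_stepped_field(curved, volts, cfg)
  expect_true(fit$nonlinear_flag)
  expect_lt(fit$r_squared, 0.99)
  quad <- 5e3 * (1 / volts)^2
  expect_true(fit_stepped_field(quad, volts, cfg,
                                r2_flag = 0.995)$nonlinear_flag)
  expect_error(fit_stepped_field(rev(curved), volts, cfg), "slope")
  expect_error(fit_stepped_field(quad[1:2], volts[1:2], cfg), "3 distinct")
})

test_that("Mason-Schamp conversion matches an independent evaluation", {
  set.seed(72)
  for (i in 1:25) {
    cfg <- instrument_config(temperature = runif(1, 200, 400),
                             pressure = runif(1, 100, 2000),
                             buffer_gas_mass = sample(c(4.002602, 28.0134), 1))
    z <- sample(1:10, 1); mass <- runif(1, 300, 20000)
    K <- runif(1, 1e-4, 1e-1)
    ms <- mobility_to_ccs(K, cfg, z, mass)
    # independently coded Mason-Schamp in SI
    mu <- (mass * cfg$buffer_gas_mass) / (mass + cfg$buffer_gas_mass) * AMU
    N <- cfg$pressure / (KB * cfg$temperature)
    omega <- 3 * z * QE / (16 * N) *
      sqrt(2 * pi / (mu * KB * cfg$temperature)) / K * 1e20
    expect_equal(ms$ccs, omega, tolerance = 1e-12)
    expect_equal(ms$K0, K * (cfg$pressure / 101325) *
                   (273.15 / cfg$temperature), tolerance = 1e-12)
    # round trip to 12 digits
    expect_equal(ccs_to_mobility(ms$ccs, cfg, z, mass), K,
                 tolerance = 1e-12)
  }
  # monotonicities of the closed form
  cfg <- instrument_config()
  expect_equal(mobility_to_ccs(2e-3, cfg, 1L, 1000)$ccs /
                 mobility_to_ccs(1e-3, cfg, 1L, 1000)$ccs, 0.5,
               tolerance = 1e-12)
  # at fixed gas number density, CCS falls as 1/sqrt(T); scale pressure
  # with T to hold N constant
  hot <- instrument_config(temperature = 400, pressure = 400 * 400 / 298)
  expect_equal(mobility_to_ccs(1e-3, hot, 1L, 1000)$ccs /
                 mobility_to_ccs(1e-3, cfg, 1L, 1000)$ccs,
               sqrt(298 / 400), tolerance = 1e-12)
})

test_that("component linking reproduces ground truth identity on a series", {
  scn <- protein_scenario(noise = "none")
  ser <- simulate_voltage_series(scn, c(100, 140, 180))
  thetas <- lapply(ser, `[[`, "truth")
  links <- link_components(thetas)
  expect_true(all(links == matrix(1:3, 3, 3)))
  # nearest-center mode suits series with small shifts (CIU-like), where
  # it must agree with the rank-based linking
  close_volts <- simulate_voltage_series(scn, c(150, 152, 154))
  close_thetas <- lapply(close_volts, `[[`, "truth")
  expect_identical(link_components(close_thetas, mode = "nearest_center"),
                   link_components(close_thetas))
  # invariant to a uniform time shift
  shifted <- lapply(thetas, function(t)
    components(t$amplitude, t$center + 1e-3, t$variance))
  expect_identical(link_components(shifted), links)
  # k = 1 trivial link
  one <- lapply(1:3, function(i) components(100, 5e-3, 1e-8))
  expect_true(all(link_components(one) == 1L))
  # unequal dimensions is a structured error
  bad <- thetas; bad[[2]] <- components(1, 5e-3, 1e-8)
  expect_error(link_components(bad), "unequal")
})

test_that("full stepped-field CCS table recovers simulated ground truth", {
  scn <- protein_scenario(noise = "none")
  volts <- c(100, 120, 140, 160, 180, 200)
  ser <- simulate_voltage_series(scn, volts)
  thetas <- lapply(ser, `[[`, "truth")
  suppressWarnings(
    tab <- ccs_table(thetas, volts, scn$cfg, charge = 7L, ion_mass = 12360))
  expect_identical(names(tab),
                   c("component", "K", "K0", "CCS", "CCS_error", "R2",
                     "fraction"))
  K_by_center <- sort(scn$mobility, decreasing = TRUE)
  expect_equal(tab$K, K_by_center, tolerance = 1e-10)
  expect_true(all(tab$R2 > 0.999))
  ccs_truth <- vapply(K_by_center, function(K)
    mobility_to_ccs(K, scn$cfg, 7L, 12360)$ccs, 0)
  expect_equal(tab$CCS, ccs_truth, tolerance = 1e-10)
  expect_equal(tab$fraction, scn$n_ions[order(scn$mobility,
                                              decreasing = TRUE)] /
                 sum(scn$n_ions), tolerance = 1e-12)
})

test_that("background components are flagged by width and amplitude", {
  cfg <- instrument_config(); pr <- prior_config()
  s2 <- sigma2_min(cfg, 7L, c(8e4, 5e3, 6e4), c(5.5e-3, 6.3e-3, 7.2e-3))
  th <- components(c(8e4, 5e3, 6e4), c(5.5e-3, 6.3e-3, 7.2e-3),
                   c(s2[1], 16 * s2[2], s2[3]))
  flags <- flag_background(th, cfg, pr, charge = 7L)
  expect_identical(flags, c(FALSE, TRUE, FALSE))
})

test_that("CIU tracking reports constructed appearance/disappearance events", {
  base <- components(c(100, 200, 150), c(5e-3, 6e-3, 7e-3), rep(1e-8, 3))
  drop3 <- components(c(100, 200), c(5e-3, 6.2e-3), rep(1e-8, 2))
  res <- list(list(voltage = 0, theta = base),
              list(voltage = 3, theta = base),
              list(voltage = 6, theta = drop3),
              list(voltage = 9, theta = drop3),
              list(voltage = 12, theta = drop3))
  tr <- track_ciu(res)
  expect_equal(tr$dimension, c(3L, 3L, 2L, 2L, 2L))
  per_track <- split(tr$tracks$voltage, tr$tracks$track)
  # exactly one track ends when the compact component disappears at 6 V
  ends_at_3V <- vapply(per_track, function(v) max(v) == 3, TRUE)
  expect_equal(sum(ends_at_3V), 1L)
  expect_equal(length(per_track), 3L)
  # the injected +0.2 ms shift of component 2 is reported to the grid
  s <- tr$shifts
  shift_23 <- s$shift[s$from_voltage == 3 & s$to_voltage == 6 & s$track == 2]
  expect_equal(shift_23, 0.2e-3, tolerance = 1e-12)
  # identical ensembles: all tracks full length with zero shift
  const <- lapply(c(0, 3, 6, 9, 12), function(v) list(voltage = v, theta = base))
  tr2 <- track_ciu(const)
  expect_true(all(tr2$shifts$shift == 0))
  expect_equal(length(unique(tr2$tracks$track)), 3L)
  expect_true(all(table(tr2$tracks$track) == 5))
})
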