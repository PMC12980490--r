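test_that("broadening variance formulas match independent SI arithmetic", {
  set.seed(101)
  for (i in 1:100) {
    cfg <- instrument_config(drift_length = runif(1, 0.1, 1),
                             drift_voltage = runif(1, 50, 500),
                             temperature = runif(1, 200, 400),
                             pressure = runif(1, 100, 1000),
                             injection_pulse = runif(1, 1e-5, 5e-4),
                             coulomb_factor = runif(1, 0.1, 2))
    z <- sample(1:20, 1); N <- runif(1, 0, 1e6); t <- runif(1, 1e-3, 2e-2)
    expect_equal(sigma2_diffusion(cfg, z, t),
                 2 * KB * cfg$temperature / (z * QE * cfg$drift_voltage) * t^2,
                 tolerance = 1e-10)
    Q <- z * QE * N
    expect_equal(sigma2_coulomb(cfg, z, N, t),
                 cfg$coulomb_factor *
                   (3 * Q / (4 * pi * EPS0 * cfg$drift_voltage *
                               cfg$drift_length))^(2 / 3) * t^2,
                 tolerance = 1e-10)
    expect_equal(sigma2_injection(cfg), cfg$injection_pulse^2 / 12,
                 tolerance = 1e-10)
    expect_equal(sigma2_min(cfg, z, N, t),
                 sigma2_injection(cfg) + sigma2_coulomb(cfg, z, N, t) +
                   sigma2_diffusion(cfg, z, t),
                 tolerance = 1e-10)
  }
})

test_that("variance formulas reproduce reference values and scalings", {
  cfg <- instrument_config(drift_voltage = 100, temperature = 298)
  # 2 kB 298 / (e * 100) * (1e-2)^2, frozen from hand SI arithmetic
  expect_equal(sigma2_diffusion(cfg, 1L, 10e-3), 5.135931e-08,
               tolerance = 1e-6)
  expect_equal(sigma2_diffusion(cfg, 1L, 0), 0)
  expect_equal(sigma2_diffusion(cfg, 1L, 20e-3) /
                 sigma2_diffusion(cfg, 1L, 10e-3), 4)
  expect_equal(sigma2_injection(instrument_config(injection_pulse = 100e-6)),
               8.333333e-10, tolerance = 1e-6)
  expect_equal(sigma2_coulomb(cfg, 1L, 0, 5e-3), 0)
  expect_equal(sigma2_coulomb(cfg, 2L, 2e5, 5e-3) /
                 sigma2_coulomb(cfg, 2L, 1e5, 5e-3), 2^(2 / 3))
  expect_error(sigma2_diffusion(cfg, 0L, 1e-3), "charge")
})

test_that("sigma2_min is monotone in its physical drivers", {
  base <- list(drift_length = 0.25, drift_voltage = 150, temperature = 300,
               injection_pulse = 1e-4)
  f <- function(dV = 150, temp = 300, tinj = 1e-4, z = 5L, N = 5e4, t = 6e-3)
    sigma2_min(instrument_config(drift_voltage = dV, temperature = temp,
                                 injection_pulse = tinj), z, N, t)
  expect_gt(f(t = 8e-3), f(t = 6e-3))
  expect_gt(f(N = 1e5), f(N = 5e4))
  expect_gt(f(tinj = 2e-4), f())
  expect_gt(f(temp = 350), f())
  expect_lt(f(dV = 300), f())
  # charge: diffusion shrinks as 1/z, but the Coulomb term grows as
  # z^(2/3) at fixed ion count, so the infimum is only monotone
  # decreasing in z for a dilute (diffusion-dominated) cloud
  expect_lt(f(z = 10L, N = 0), f(z = 5L, N = 0))
})

test_that("mixture model evaluates the Gaussian sum with negative exponent", {
  th <- components(1000, 10e-3, (0.5e-3)^2)
  expect_equal(mixture_model(10e-3, th), 1000 / (0.5e-3 * sqrt(2 * pi)),
               tolerance = 1e-12)
  # far tails vanish
  expect_lt(mixture_model(10e-3 + 11 * 0.5e-3, th),
            1e-20 * mixture_model(10e-3, th))
  # Gaussian normalization: trapezoid integral returns total amplitude
  th3 <- components(c(500, 1200, 800), c(5e-3, 6e-3, 7.5e-3),
                    c(1e-8, 2e-8, 1.5e-8))
  g <- seq(2e-3, 11e-3, length.out = 4000)
  y <- mixture_model(g, th3)
  integral <- sum((y[-1] + y[-length(y)]) / 2 * diff(g))
  expect_equal(integral, 2500, tolerance = 1e-3)
  expect_error(components(1000, 10e-3, -1e-8), "variance")
})

test_that("prior on the width multiplier is a shifted exponential", {
  pr <- prior_config(lambda_rate = 35)
  expect_equal(prior_density_m(0.99, pr), 0)
  expect_equal(prior_density_m(1, pr), 35)
  expect_equal(prior_density_m(1.1, pr), 35 * exp(-3.5), tolerance = 1e-12)
  # normalization by adaptive quadrature
  igr <- stats::integrate(prior_density_m, 1, Inf, prior = pr,
                          rel.tol = 1e-10)
  expect_equal(igr$value, 1, tolerance = 1e-8)
})

test_that("log posterior enforces the hard physics constraints", {
  scn <- two_comp_scenario()
  sim <- simulate_atd(scn, seed = 5)
  cfg <- scn$cfg; pr <- scn$prior
  lp0 <- log_posterior(sim$truth, sim$atd, cfg, pr, charge = 7L)
  expect_true(is.finite(lp0))

  # center outside the sampling window
  out <- sim$truth
  out$center[1] <- sim$atd$window[1] - 1e-3
  expect_identical(log_posterior(components(out$amplitude, out$center,
                                            out$variance),
                                 sim$atd, cfg, pr, charge = 7L), -Inf)

  # variance below the physics infimum
  tight <- sim$truth
  tight$variance[2] <- 0.5 * sigma2_min(cfg, 7L, tight$amplitude[2],
                                        tight$center[2])
  expect_identical(log_posterior(components(tight$amplitude, tight$center,
                                            tight$variance),
                                 sim$atd, cfg, pr, charge = 7L), -Inf)

  # permutation invariance: components() sorts, so shuffled input matches
  perm <- components(rev(sim$truth$amplitude), rev(sim$truth$center),
                     rev(sim$truth$variance))
  expect_equal(log_posterior(perm, sim$atd, cfg, pr, charge = 7L), lp0)
})

test_that("noiseless truth is a local maximum of the log posterior", {
  scn <- two_comp_scenario(noise = "none")
  sim <- simulate_atd(scn, seed = 2)
  cfg <- scn$cfg; pr <- scn$prior
  truth <- sim$truth
  lp0 <- log_posterior(truth, sim$atd, cfg, pr, charge = 7L)
  # grid perturbation scan around the generating parameters; the truth has
  # m = 1 so only upward variance perturbations stay feasible
  for (i in 1:2) {
    for (eps in c(-0.02, 0.02)) {
      th <- truth; th$center[i] <- th$center[i] * (1 + eps / 10)
      expect_lt(log_posterior(components(th$amplitude, th$center, th$variance),
                              sim$atd, cfg, pr, charge = 7L), lp0)
      th <- truth; th$amplitude[i] <- th$amplitude[i] * (1 + eps)
      expect_lt(log_posterior(components(th$amplitude, th$center, th$variance),
                              sim$atd, cfg, pr, charge = 7L), lp0)
    }
    th <- truth; th$variance[i] <- th$variance[i] * 1.05
    expect_lt(log_posterior(components(th$amplitude, th$center, th$variance),
                            sim$atd, cfg, pr, charge = 7L), lp0)
  }
})
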