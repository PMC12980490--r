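test_that("amplitude/center proposal is symmetric and picks components uniformly", {
  th <- components(c(500, 800, 300), c(5e-3, 6e-3, 7e-3), rep(2e-8, 3))
  scales <- list(amplitude = 20, center = 5e-5)
  set.seed(21)
  n <- 1e4
  picked <- integer(n); dmu <- numeric(n)
  for (i in seq_len(n)) {
    pr <- propose_amplitude_center(th, scales)
    picked[i] <- pr$index
    dmu[i] <- sum(pr$theta$center) - sum(th$center)  # net displacement
  }
  # mean center displacement ~ 0 (symmetric kernel)
  expect_lt(abs(mean(dmu)), 3 * stats::sd(dmu) / sqrt(n))
  # degenerate scales leave theta unchanged
  same <- propose_amplitude_center(th, list(amplitude = 0, center = 0))
  expect_equal(same$theta$center, th$center)
  expect_equal(same$theta$amplitude, th$amplitude)
  # uniform component choice (the index reported is post-sort; with small
  # scales the sort is stable, so it matches the drawn component)
  freq <- tabulate(picked, 3) / n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * se + 1e-3))
})

test_that("width proposal draws m from the shifted exponential at the infimum", {
  cfg <- instrument_config()
  pr <- prior_config(lambda_rate = 35)
  th <- list(amplitude = c(500, 800), center = c(5e-3, 6e-3),
             variance = rep(2e-8, 2), k = 2L)
  set.seed(22)
  n <- 1e5
  ms <- vapply(seq_len(n), function(i)
    propose_sigma(th, 1L, pr, cfg, charge = 7L)$m, 0)
  expect_true(all(ms >= 1))
  expect_lt(abs(mean(ms) - (1 + 1 / 35)), 3 * stats::sd(ms) / sqrt(n))
  # the variance is m^2 times the infimum at the component's (A, mu)
  set.seed(23)
  out <- propose_sigma(th, 2L, pr, cfg, charge = 7L)
  expect_equal(out$theta$variance[2],
               out$m^2 * sigma2_min(cfg, 7L, 800 * pr$ions_per_count, 6e-3),
               tolerance = 1e-12)
  # large lambda degenerates to the infimum
  pr_stiff <- prior_config(lambda_rate = 1e8)
  out2 <- propose_sigma(th, 1L, pr_stiff, cfg, charge = 7L)
  expect_equal(out2$theta$variance[1],
               sigma2_min(cfg, 7L, 500, 5e-3), tolerance = 1e-6)
})

test_that("plain chain recovers standard normal moments", {
  set.seed(31)
  r <- ee_sample(function(x) 0.5 * x^2, init = 0,
                 ladder = ladder_config(temperatures = 1,
                                        steps_per_level = 2e4),
                 scales = 2.4)
  x <- as.vector(r$samples)
  n_eff <- 2e4 / 20  # conservative autocorrelation allowance
  expect_lt(abs(mean(x)), 3 / sqrt(n_eff))
  expect_lt(abs(stats::var(x) - 1), 3 * sqrt(2) / sqrt(n_eff))
})

test_that("equi-energy swap preserves the stationary law on a 3-state toy", {
  # States with energies E; two levels T1 = 1, T2 = 4. The cold chain
  # alternates a local symmetric move with an EE-style swap against an iid
  # store from the hot chain, restricted to the same energy ring (ring 1 =
  # states a, b; ring 2 = state c). The stationary law must stay
  # proportional to exp(-E).
  E <- c(a = 0, b = 0.4, c = 2.5)
  T2 <- 4
  p_hot <- exp(-E / T2) / sum(exp(-E / T2))
  ring <- c(1L, 1L, 2L)
  p_target <- exp(-E) / sum(exp(-E))
  set.seed(33)
  n <- 4e5
  state <- 1L
  counts <- c(0L, 0L, 0L)
  u_move <- stats::runif(n); u_acc <- stats::runif(n)
  pick3 <- sample.int(3L, n, replace = TRUE)
  hot_draws <- sample.int(3L, n, replace = TRUE, prob = p_hot)
  for (i in seq_len(n)) {
    if (u_move[i] < 0.5) {   # symmetric local move: uniform over states
      j <- pick3[i]
      if (u_acc[i] < exp(E[state] - E[j])) state <- j
    } else {                 # EE swap within the ring
      j <- hot_draws[i]
      if (ring[j] == ring[state] &&
          u_acc[i] < exp((E[state] - E[j]) * (1 - 1 / T2))) state <- j
    }
    counts[state] <- counts[state] + 1L
  }
  tv <- 0.5 * sum(abs(counts / n - p_target))
  expect_lt(tv, 5e-3)
})

test_that("tempered ladder crosses barriers a single chain cannot", {
  en <- function(x) -log(0.5 * stats::dnorm(x, -4, 0.5) +
                           0.5 * stats::dnorm(x, 4, 0.5))
  set.seed(34)
  r_single <- ee_sample(en, init = -4,
                        ladder = ladder_config(temperatures = 1,
                                               steps_per_level = 2e4),
                        scales = 0.5, adapt = FALSE)
  expect_equal(mean(r_single$samples > 0), 0)   # trapped in the left mode
  set.seed(34)
  r_ee <- ee_sample(en, init = -4,
                    ladder = ladder_config(steps_per_level = 2e4),
                    scales = 0.5, adapt = FALSE)
  frac <- mean(r_ee$samples > 0)
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
})

test_that("ATD posterior samples satisfy every hard constraint", {
  scn <- two_comp_scenario(noise = "poisson")
  sim <- simulate_atd(scn, seed = 41)
  set.seed(42)
  es <- run_equi_energy(sim$atd, 2, test_ladder(), cfg = scn$cfg,
                        prior = scn$prior, charge = 7L)
  A <- es$samples[, 1:2]; mu <- es$samples[, 3:4]; m <- es$samples[, 5:6]
  w <- sim$atd$window
  expect_true(all(A >= 0))
  expect_true(all(mu > w[1] & mu < w[2]))
  expect_true(all(m >= 1))
  # center-sorted storage, no label switching
  expect_true(all(mu[, 1] <= mu[, 2]))
  # energies are consistent with the public log-posterior on a spot check
  i <- which.min(es$energies)
  th <- imsdeconv:::state_to_components(es$samples[i, ], 2L, scn$cfg,
                                        scn$prior, 7L)
  expect_equal(-es$energies[i],
               log_posterior(th, sim$atd, scn$cfg, scn$prior, charge = 7L),
               tolerance = 1e-8)
})

test_that("noiseless two-component ATD is recovered to sub-percent accuracy", {
  scn <- two_comp_scenario(noise = "none")
  sim <- simulate_atd(scn)
  set.seed(7)
  es <- run_equi_energy(sim$atd, 2, test_ladder(2000), cfg = scn$cfg,
                        prior = scn$prior, charge = 7L)
  cm <- colMeans(es$samples)
  expect_lt(max(abs(cm[3:4] - sim$truth$center) / sim$truth$center), 0.005)
})
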