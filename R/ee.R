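#' Configuration of the equi-energy temperature ladder
#'
#' The sampler runs a ladder of Metropolis chains targeting
#' \eqn{\pi^{1/T}} at temperatures T descending to 1, with equi-energy
#' jumps: a chain may propose to swap its state for a stored state of the
#' next-hotter chain lying in the same energy ring, which lets
#' low-temperature chains cross energy barriers.
#'
#' @param n_levels Number of temperature levels (>= 2 for tempering; 1 is
#'   allowed and reduces to plain Metropolis-Hastings).
#' @param temperatures Ascending temperatures, first equal to 1 (the
#'   target). Default: geometric ladder with ratio sqrt(10).
#' @param energy_cutoffs Ascending energy ring boundaries. Default `NULL`:
#'   set from the 20/40/60/80% quantiles of the hottest (pilot) chain's
#'   energies.
#' @param ee_jump_prob Probability of attempting an equi-energy jump
#'   instead of a local move (levels below the hottest).
#' @param steps_per_level MCMC steps per level.
#' @param burn_in_fraction Fraction of each level discarded and used for
#'   proposal-scale adaptation.
#' @param seed Optional integer seed used by [ee_sample()].
#' @return Object of class `"ladder_config"`.
#' @export
ladder_config <- function(n_levels = 5, temperatures = NULL,
                          energy_cutoffs = NULL, ee_jump_prob = 0.1,
                          steps_per_level = 2000, burn_in_fraction = 0.2,
                          seed = NULL) {
  if (is.null(temperatures)) temperatures <- sqrt(10)^(seq_len(n_levels) - 1)
  n_levels <- length(temperatures)
  if (n_levels < 1L) stop("ladder_config: need at least one level")
  if (abs(temperatures[1] - 1) > 1e-12)
    stop("ladder_config: first temperature must be 1 (the target)")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("ladder_config: temperatures must be strictly ascending")
  if (ee_jump_prob <= 0 || ee_jump_prob >= 1)
    stop("ladder_config: ee_jump_prob must be in (0, 1)")
  if (!is.null(energy_cutoffs) && is.unsorted(energy_cutoffs, strictly = TRUE))
    stop("ladder_config: energy_cutoffs must be strictly ascending")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("ladder_config: burn_in_fraction must be in [0, 1)")
  structure(list(n_levels = n_levels, temperatures = temperatures,
                 energy_cutoffs = energy_cutoffs,
                 ee_jump_prob = ee_jump_prob,
                 steps_per_level = as.integer(steps_per_level),
                 burn_in_fraction = burn_in_fraction, seed = seed),
            class = "ladder_config")
}

# default symmetric random-walk proposal; `scale_mult` is the adapted
# multiplier applied to the base scales
.rw_propose <- function(state, scales) {
  list(state = state + stats::rnorm(length(state), 0, scales), log_q_ratio = 0)
}

#' Equi-energy sampler over a generic energy function
#'
#' Generic engine underlying [run_equi_energy()]. Runs the ladder from the
#' hottest level down; each level's chain stores its states binned into
#' energy rings, and the next-cooler level proposes equi-energy swaps into
#' those stored states. Only post-burn-in samples of the T = 1 chain are
#' returned as draws from the target.
#'
#' @param energy Function(state) returning the energy, i.e. the negative
#'   unnormalized log target density. May return `Inf` for excluded states.
#' @param init Numeric starting state with finite energy.
#' @param ladder A [ladder_config()].
#' @param scales Base proposal scales (recycled to the state length) for
#'   the default random-walk proposal, or passed to `propose`.
#' @param propose Function(state, scales) returning
#'   `list(state=, log_q_ratio=)` where `log_q_ratio` is
#'   log q(state'|state) - log q(state|state') contributions that do not
#'   cancel. Default: symmetric Gaussian random walk (ratio 0).
#' @param adapt Adapt a global scale multiplier toward 25-40% local
#'   acceptance during each level's burn-in (frozen afterwards).
#' @return List with `samples` (matrix, post-burn-in T = 1 states),
#'   `energies`, `acceptance` (per-level local and equi-energy rates),
#'   `cutoffs`, `ee_fallbacks` (jumps attempted with an empty ring),
#'   `scale_mult` (final adapted multiplier).
#' @export
ee_sample <- function(energy, init, ladder = ladder_config(),
                      scales = 1, propose = .rw_propose, adapt = TRUE) {
  if (!is.null(ladder$seed)) set.seed(ladder$seed)
  d <- length(init)
  scales <- rep_len(scales, d)
  e0 <- energy(init)
  if (!is.finite(e0)) stop("ee_sample: init state has non-finite energy")
  nl <- ladder$n_levels
  temps <- ladder$temperatures
  n_steps <- ladder$steps_per_level
  n_burn <- floor(ladder$burn_in_fraction * n_steps)
  cutoffs <- ladder$energy_cutoffs
  stored <- vector("list", nl)        # per level: list(states=matrix, energies, ring)
  acc <- matrix(0, nl, 2, dimnames = list(NULL, c("local", "ee")))
  att <- matrix(0, nl, 2, dimnames = list(NULL, c("local", "ee")))
  ee_fallbacks <- 0L
  mult <- 1
  state <- init; e_cur <- e0

  for (lev in nl:1) {
    temp <- temps[lev]
    S <- matrix(NA_real_, n_steps, d)
    E <- numeric(n_steps)
    higher <- if (lev < nl) stored[[lev + 1]] else NULL
    # a tempered target is ~sqrt(T) wider than the cold one, so the local
    # step size follows suit unless the scales are re-estimated below
    lev_fac <- sqrt(temp)
    if (adapt && !is.null(higher)) {
      # re-estimate per-coordinate proposal scales from the hotter chain's
      # spread: the tempered target narrows as T drops, and one global
      # multiplier cannot serve parameter blocks of very different scale
      sds <- apply(higher$states, 2, stats::sd)
      scales <- ifelse(sds > 0, sds, scales)
      mult <- 1
      lev_fac <- 1
    }
    n_acc_win <- 0L; n_att_win <- 0L
    for (s in seq_len(n_steps)) {
      do_ee <- !is.null(higher) && stats::runif(1) < ladder$ee_jump_prob
      if (do_ee) {
        ring <- findInterval(e_cur, cutoffs) + 1L
        idx <- which(higher$ring == ring)
        if (length(idx) == 0L) {
          ee_fallbacks <- ee_fallbacks + 1L
          do_ee <- FALSE
        } else {
          att[lev, "ee"] <- att[lev, "ee"] + 1
          j <- idx[sample.int(length(idx), 1L)]
          e_new <- higher$energies[j]
          # Kou-style swap: ratio pi_l(y) pi_{l+1}(x) / (pi_l(x) pi_{l+1}(y))
          log_a <- (e_cur - e_new) * (1 / temp - 1 / temps[lev + 1])
          if (log(stats::runif(1)) < log_a) {
            state <- higher$states[j, ]
            e_cur <- e_new
            acc[lev, "ee"] <- acc[lev, "ee"] + 1
          }
        }
      }
      if (!do_ee) {
        att[lev, "local"] <- att[lev, "local"] + 1
        n_att_win <- n_att_win + 1L
        prop <- propose(state, scales * (mult * lev_fac))
        e_new <- energy(prop$state)
        log_a <- (e_cur - e_new) / temp + prop$log_q_ratio
        if (is.finite(e_new) && log(stats::runif(1)) < log_a) {
          state <- prop$state
          e_cur <- e_new
          acc[lev, "local"] <- acc[lev, "local"] + 1
          n_acc_win <- n_acc_win + 1L
        }
        if (adapt && s <= n_burn && n_att_win >= 25L) {
          r <- n_acc_win / n_att_win
          if (r > 0.40) mult <- mult * 1.4
          else if (r < 0.25) mult <- mult * 0.6
          n_acc_win <- 0L; n_att_win <- 0L
        }
      }
      S[s, ] <- state
      E[s] <- e_cur
    }
    if (is.null(cutoffs)) {  # hottest level doubles as the ring pilot
      cutoffs <- unique(stats::quantile(E, c(0.2, 0.4, 0.6, 0.8), names = FALSE))
    }
    keep <- (n_burn + 1L):n_steps
    stored[[lev]] <- list(states = S[keep, , drop = FALSE],
                          energies = E[keep],
                          ring = findInterval(E[keep], cutoffs) + 1L)
    if (lev > 1L) {  # next (cooler) chain starts from this level's best state
      i_best <- which.min(E)
      state <- S[i_best, ]
      e_cur <- E[i_best]
    }
  }
  rates <- acc / pmax(att, 1)
  list(samples = stored[[1]]$states, energies = stored[[1]]$energies,
       acceptance = rates, cutoffs = cutoffs, ee_fallbacks = ee_fallbacks,
       scale_mult = mult)
}

#' Propose new amplitude and center for one component
#'
#' First half of the joint two-step parameter update: one uniformly chosen
#' component's amplitude and center are perturbed by zero-mean Gaussian
#' draws (a symmetric kernel).
#'
#' @param theta A [components()] object.
#' @param scales `list(amplitude=, center=)` proposal standard deviations.
#' @return List with `theta` (perturbed, re-sorted by center) and `index`
#'   (the perturbed component's position after sorting).
#' @export
propose_amplitude_center <- function(theta, scales) {
  theta <- as_components(theta)
  i <- sample.int(theta$k, 1L)
  A <- theta$amplitude; mu <- theta$center
  A[i] <- A[i] + stats::rnorm(1, 0, scales$amplitude)
  mu[i] <- mu[i] + stats::rnorm(1, 0, scales$center)
  o <- order(mu)
  list(theta = list(amplitude = A[o], center = mu[o],
                    variance = theta$variance[o], k = theta$k),
       index = which(o == i))
}

#' Propose a new variance for one component
#'
#' Second half of the joint update: the width multiplier m is redrawn from
#' the shifted-exponential prior and the variance set to
#' m^2 * [sigma2_min()] recomputed at the component's updated amplitude and
#' center.
#'
#' @param theta Output `theta` of [propose_amplitude_center()] (a plain
#'   list is accepted; amplitudes may be temporarily negative, rejection
#'   happens in the acceptance step).
#' @param index Component whose variance is redrawn.
#' @param prior A [prior_config()].
#' @param cfg An [instrument_config()].
#' @param charge Ion charge state.
#' @return List with `theta` and `m` (the drawn multiplier).
#' @export
propose_sigma <- function(theta, index, prior, cfg, charge = 1L) {
  m <- 1 + stats::rexp(1, prior$lambda_rate)
  n_ions <- max(theta$amplitude[index], 0) * prior$ions_per_count
  theta$variance[index] <-
    m^2 * sigma2_min(cfg, charge, n_ions, max(theta$center[index], 0))
  list(theta = theta, m = m)
}

# internal local kernel on the state vector c(A, mu, m): a mixture of
# (i) the joint two-step move - one component's (A, mu) perturbed by a
# symmetric normal, its m redrawn from the shifted-exponential prior - and
# (ii) for k >= 2, a symmetric amplitude transfer between two components
# (sum-preserving; overlapping components make this the slow ridge
# direction that single-component moves cannot follow). Both moves are
# locally balanced; the returned log_q_ratio carries the only
# non-cancelling proposal term (the independence redraw of m).
.atd_propose <- function(k, lambda, transfer_prob = 0.3) {
  force(k); force(lambda); force(transfer_prob)
  function(state, scales) {
    A <- state[seq_len(k)]; mu <- state[k + seq_len(k)]
    m <- state[2L * k + seq_len(k)]
    if (k >= 2L && stats::runif(1) < transfer_prob) {
      ij <- sample.int(k, 2L)
      delta <- stats::rnorm(1, 0, scales[ij[1]])
      A[ij[1]] <- A[ij[1]] + delta
      A[ij[2]] <- A[ij[2]] - delta
      return(list(state = c(A, mu, m), log_q_ratio = 0))
    }
    i <- sample.int(k, 1L)
    A[i] <- A[i] + stats::rnorm(1, 0, scales[i])
    mu[i] <- mu[i] + stats::rnorm(1, 0, scales[k + i])
    m_old <- m[i]
    m[i] <- 1 + stats::rexp(1, lambda)
    o <- order(mu)
    # q includes the prior density of the redrawn m; its ratio contributes
    # lambda * (m_new - m_old) to the log acceptance
    list(state = c(A[o], mu[o], m[o]),
         log_q_ratio = lambda * (m[i] - m_old))
  }
}

# initial state: centers at equal quantiles of cumulative intensity,
# amplitudes from local mass, m = 1.2
.atd_init <- function(atd, k) {
  cum <- cumsum(atd$intensities)
  q <- (seq_len(k) - 0.5) / k
  centers <- sapply(q, function(p) atd$times[which.max(cum >= p * cum[length(cum)])])
  w <- atd$window
  centers <- pmin(pmax(centers, w[1] + atd$dt), w[2] - atd$dt)
  centers <- centers + seq_len(k) * 1e-9  # break exact ties
  A <- rep(sum(atd$intensities) / k, k)
  c(A, centers, rep(1.2, k))
}

#' Sample the fixed-dimension ATD posterior with the equi-energy sampler
#'
#' Infers Pr(Theta_k | k, X) for a fixed number of components k. The local
#' move is the joint two-step update ([propose_amplitude_center()] then
#' [propose_sigma()]); tempering and equi-energy jumps follow
#' [ee_sample()]. Samples are stored center-sorted in the coordinates
#' (A_1..A_k, mu_1..mu_k, m_1..m_k).
#'
#' @param atd An [atd()] object.
#' @param k Number of components.
#' @param ladder A [ladder_config()].
#' @param cfg An [instrument_config()].
#' @param prior A [prior_config()].
#' @param charge Ion charge state.
#' @return Object of class `"ee_samples"`: `dimension`, `samples` (matrix
#'   n x 3k), `energies`, `acceptance`, `ess` (effective sample size per
#'   parameter), `map` (lowest-energy state), plus the physics context.
#' @export
run_equi_energy <- function(atd, k, ladder = ladder_config(),
                            cfg = instrument_config(),
                            prior = prior_config(), charge = 1L) {
  stopifnot(k >= 1L)
  s_noise <- noise_scale(atd, prior)
  energy <- function(st) -.log_post_state(st, k, atd, cfg, prior, charge,
                                          s = s_noise)
  init <- .atd_init(atd, k)
  w <- atd$window
  scales <- c(rep(0.05 * max(init[seq_len(k)]), k),     # amplitudes
              rep(0.02 * (w[2] - w[1]), k),             # centers
              rep(1, k))                                # m (redrawn, unused)
  res <- ee_sample(energy, init, ladder, scales = scales,
                   propose = .atd_propose(k, prior$lambda_rate))
  colnames(res$samples) <- c(paste0("A", seq_len(k)), paste0("mu", seq_len(k)),
                             paste0("m", seq_len(k)))
  i_map <- which.min(res$energies)
  structure(list(dimension = k, samples = res$samples,
                 energies = res$energies, acceptance = res$acceptance,
                 ess = apply(res$samples, 2, .ess),
                 map = res$samples[i_map, ],
                 cutoffs = res$cutoffs, ee_fallbacks = res$ee_fallbacks,
                 cfg = cfg, prior = prior, charge = charge,
                 noise_scale = s_noise),
            class = "ee_samples")
}

#' @export
print.ee_samples <- function(x, ...) {
  cat(sprintf("Equi-energy posterior sample set: k = %d, %d samples\n",
              x$dimension, nrow(x$samples)))
  cat(sprintf("  min energy %.4g; local acceptance (T=1) %.2f; min ESS %.0f\n",
              min(x$energies), x$acceptance[1, "local"], min(x$ess)))
  invisible(x)
}

# initial-sequence-style ESS: truncate autocorrelation at first negative lag
.ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}
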