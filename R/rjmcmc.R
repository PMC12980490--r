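# Reversible-jump MCMC over the number of mixture components, using the
# BSP-discretized fixed-dimension posteriors as independence proposals.
# Because proposed parameter vectors are drawn whole from the target
# dimension's tree, the dimension-matching Jacobian is 1 and the acceptance
# ratio only involves posterior and proposal densities.

#' Reversible-jump MCMC over a set of per-dimension proposal trees
#'
#' Generic engine underlying [run_rjmcmc()]. At each step, with probability
#' `refresh_prob` the chain refreshes the parameters within the current
#' dimension (an independence draw from that dimension's tree); otherwise
#' it proposes a dimension jump k -> k +/- 1 (probability 1/2 each,
#' rejected at the range ends) with the new parameter vector drawn from the
#' destination tree. Acceptance uses the unnormalized target times the
#' dimension prior over the BSP proposal densities.
#'
#' @param log_target Function(k, theta) returning the unnormalized log
#'   posterior density of theta within model dimension k (may be `-Inf`).
#' @param trees Named list of [build_partition()] trees; names are the
#'   dimensions (a contiguous integer range).
#' @param log_dim_prior Function(k) giving the log prior over dimensions
#'   (default flat).
#' @param n_steps Number of RJMCMC steps.
#' @param refresh_prob Probability of a within-dimension refresh move.
#' @param burn_in_fraction Fraction of steps discarded before computing
#'   visit frequencies.
#' @param seed Optional integer seed.
#' @param init_k Starting dimension (default the lowest).
#' @return Object of class `"dim_posterior"`: `dims`, `probabilities`,
#'   `mean_dimension`, `map_theta_per_dim` (highest-posterior state seen
#'   per dimension), `visits`, `acceptance`, `zero_density_rejects`,
#'   `n_steps`.
#' @export
rjmcmc_sample <- function(log_target, trees, log_dim_prior = function(k) 0,
                          n_steps = 20000, refresh_prob = 0.5,
                          burn_in_fraction = 0.2, seed = NULL,
                          init_k = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- sort(as.integer(names(trees)))
  if (!all(diff(dims) == 1L) && length(dims) > 1L)
    stop("rjmcmc_sample: tree dimensions must form a contiguous range")
  k_min <- dims[1]; k_max <- dims[length(dims)]
  if (is.null(init_k)) init_k <- k_min
  tr <- function(k) trees[[as.character(k)]]

  k <- init_k
  lt_cur <- -Inf
  for (try in 1:200) {   # initial state: a finite-posterior draw
    th <- sample_from(tr(k))
    lt_cur <- log_target(k, th)
    if (is.finite(lt_cur)) break
  }
  if (!is.finite(lt_cur))
    stop("rjmcmc_sample: could not initialize at a finite-posterior state")
  q_cur <- density_at(tr(k), th)

  visits <- integer(n_steps)
  best_lt <- stats::setNames(rep(-Inf, length(dims)), dims)
  best_th <- stats::setNames(vector("list", length(dims)), dims)
  acc <- c(refresh = 0, jump = 0); att <- c(refresh = 0, jump = 0)
  zero_rej <- 0L

  for (s in seq_len(n_steps)) {
    if (stats::runif(1) < refresh_prob) {
      att["refresh"] <- att["refresh"] + 1
      th_new <- sample_from(tr(k))
      lt_new <- log_target(k, th_new)
      q_new <- density_at(tr(k), th_new)
      if (is.finite(lt_new) && q_new > 0) {
        log_a <- if (q_cur > 0) lt_new - lt_cur + log(q_cur) - log(q_new)
                 else Inf  # escape from a measure-zero face
        if (log(stats::runif(1)) < log_a) {
          th <- th_new; lt_cur <- lt_new; q_cur <- q_new
          acc["refresh"] <- acc["refresh"] + 1
        }
      } else zero_rej <- zero_rej + 1L
    } else {
      att["jump"] <- att["jump"] + 1
      k_new <- k + sample(c(-1L, 1L), 1L)
      if (k_new >= k_min && k_new <= k_max) {
        th_new <- sample_from(tr(k_new))
        lt_new <- log_target(k_new, th_new)
        q_new <- density_at(tr(k_new), th_new)
        if (is.finite(lt_new) && q_new > 0) {
          log_a <- if (q_cur > 0)
            lt_new + log_dim_prior(k_new) + log(q_cur) -
              lt_cur - log_dim_prior(k) - log(q_new)
          else Inf
          if (log(stats::runif(1)) < log_a) {
            k <- k_new; th <- th_new; lt_cur <- lt_new; q_cur <- q_new
            acc["jump"] <- acc["jump"] + 1
          }
        } else zero_rej <- zero_rej + 1L
      }
    }
    visits[s] <- k
    ki <- as.character(k)
    if (lt_cur > best_lt[ki]) { best_lt[ki] <- lt_cur; best_th[[ki]] <- th }
  }
  keep <- visits[(floor(burn_in_fraction * n_steps) + 1L):n_steps]
  counts <- tabulate(factor(keep, levels = dims), nbins = length(dims))
  probs <- counts / sum(counts)
  structure(list(dims = dims, probabilities = probs,
                 mean_dimension = sum(dims * probs),
                 map_theta_per_dim = best_th, map_log_posterior = best_lt,
                 visits = counts, n_steps = n_steps,
                 acceptance = acc / pmax(att, 1),
                 zero_density_rejects = zero_rej),
            class = "dim_posterior")
}

#' @export
print.dim_posterior <- function(x, ...) {
  cat("RJMCMC dimension posterior\n")
  tab <- data.frame(k = x$dims, `Pr(k|X)` = round(x$probabilities, 4),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("  mean dimension: %.3f over %d post-burn-in steps\n",
              x$mean_dimension, sum(x$visits)))
  invisible(x)
}

#' Run RJMCMC dimension inference for an ATD
#'
#' Combines the per-dimension BSP trees with the physics-constrained ATD
#' posterior. The trans-dimensional target for dimension k is the
#' center-sorted posterior multiplied by k! (the label-permutation
#' multiplicity), so that visit frequencies estimate Pr(k | X).
#'
#' @param atd An [atd()] object.
#' @param trees Named list of [build_partition()] trees over a contiguous
#'   dimension range of width at most 4 (the supervised `[k, k + 3]`
#'   window).
#' @param cfg An [instrument_config()].
#' @param prior A [prior_config()].
#' @param charge Ion charge state.
#' @param dim_prior `"flat"` (default: dimension inference rests on the
#'   model error alone) or `"penalized"` (geometric penalty
#'   `exp(-penalty_rate * k)`).
#' @param penalty_rate Rate of the geometric penalty when
#'   `dim_prior = "penalized"`.
#' @param n_steps,refresh_prob,burn_in_fraction,seed Passed to
#'   [rjmcmc_sample()].
#' @return A `"dim_posterior"` object (see [rjmcmc_sample()]) with the
#'   physics context attached so [consensus_solution()] can return
#'   [components()].
#' @export
run_rjmcmc <- function(atd, trees, cfg = instrument_config(),
                       prior = prior_config(), charge = 1L,
                       dim_prior = c("flat", "penalized"),
                       penalty_rate = 1, n_steps = 20000,
                       refresh_prob = 0.5, burn_in_fraction = 0.2,
                       seed = NULL) {
  dim_prior <- match.arg(dim_prior)
  dims <- sort(as.integer(names(trees)))
  if (dims[length(dims)] - dims[1] > 3L)
    stop("run_rjmcmc: dimension range wider than the supervised [k, k+3] window")
  s_noise <- noise_scale(atd, prior)
  lt <- function(k, th)
    .log_post_state(th, k, atd, cfg, prior, charge, s = s_noise) + lfactorial(k)
  ldp <- if (dim_prior == "flat") function(k) 0
         else function(k) -penalty_rate * k
  dp <- rjmcmc_sample(lt, trees, log_dim_prior = ldp, n_steps = n_steps,
                      refresh_prob = refresh_prob,
                      burn_in_fraction = burn_in_fraction, seed = seed)
  dp$cfg <- cfg; dp$prior <- prior; dp$charge <- charge
  dp
}

#' Consensus deconvolution solution(s) from a dimension posterior
#'
#' @param dp A `"dim_posterior"` from [run_rjmcmc()] or [rjmcmc_sample()].
#' @param rule `"modal"` (argmax dimension), `"mean_rounded"` (mean
#'   dimension rounded), or `"both_neighbors"` (when the fractional part of
#'   the mean dimension falls inside `band`, both flanking integers are
#'   returned — the situation where the predicted value falls between two
#'   integers and both models are carried forward).
#' @param band Fractional-part band for `"both_neighbors"`.
#' @return List of one or two `list(k=, theta=)` entries; `theta` is a
#'   [components()] object when the posterior carries physics context,
#'   otherwise the raw parameter state.
#' @export
consensus_solution <- function(dp, rule = c("modal", "mean_rounded",
                                            "both_neighbors"),
                               band = c(0.3, 0.7)) {
  rule <- match.arg(rule)
  ks <- switch(rule,
    modal = dp$dims[which.max(dp$probabilities)],
    mean_rounded = as.integer(round(dp$mean_dimension)),
    both_neighbors = {
      fr <- dp$mean_dimension - floor(dp$mean_dimension)
      if (fr >= band[1] && fr <= band[2])
        c(floor(dp$mean_dimension), ceiling(dp$mean_dimension))
      else as.integer(round(dp$mean_dimension))
    })
  ks <- as.integer(intersect(ks, dp$dims))
  if (length(ks) == 0L) stop("consensus_solution: selected dimension not in range")
  lapply(ks, function(k) {
    st <- dp$map_theta_per_dim[[as.character(k)]]
    th <- if (!is.null(dp$cfg) && !is.null(st))
      state_to_components(st, k, dp$cfg, dp$prior, dp$charge) else st
    list(k = k, theta = th)
  })
}
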