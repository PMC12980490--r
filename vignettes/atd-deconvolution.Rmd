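---
title: "Physics-constrained Bayesian deconvolution of drift-tube ion mobility ATDs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-constrained Bayesian deconvolution of drift-tube ion mobility ATDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsdeconv)
```

## The problem

A drift-tube ion mobility (DTIMS) measurement records an arrival time
distribution (ATD): ion counts versus the time ions need to traverse a
uniform-field drift region. When several conformational families (or
constitutional isomers) of similar mobility contribute, the ATD is a
superposition of overlapping peaks, and two questions must be answered at
once: *how many* components are present, and *what are their* amplitudes,
centers and widths. Gradient-based fitting answers neither reliably —
solutions depend on the starting point, and nothing penalizes adding one
more peak. `imsdeconv` treats the problem as Bayesian inference over both
the parameters and the number of components, with gas-phase ion transport
theory supplying hard, physically motivated constraints.

## The model

The forward model for an ATD is a sum of $k$ Gaussian components,

$$
M(t, \Theta_k) \;=\; \sum_{i=1}^{k}
\frac{A_i}{\sigma_i\sqrt{2\pi}}
\exp\!\left(-\frac{(t-\mu_i)^2}{2\sigma_i^2}\right),
$$

with amplitude $A_i$ (total ion count of the component), mean arrival time
$\mu_i$, and temporal variance $\sigma_i^2$. Multiplied by the grid step it
predicts expected counts per bin.

### The broadening infimum

The key physical idea is that a component's width cannot be arbitrary.
Three processes set a *lower bound* on the temporal spread of an ion cloud
at arrival time $t$:

* **Injection** — a rectangular injection pulse of duration $t_{Inj}$
  enters as $\sigma^2_{Inj} = t_{Inj}^2/12$;
* **Diffusion** — $\sigma^2_{Diff} = \dfrac{2 k_B T}{z e \Delta V}\,t^2$,
  driven by temperature and drift time;
* **Coulomb repulsion** — a cloud of $N_i$ like ions acts as a macro-ion of
  charge $Q = z e N_i$ and spreads as
  $\sigma^2_{Coul} = C_{Coul}\left(\dfrac{3 Q}{4 \pi \epsilon_0 \Delta V L}\right)^{2/3} t^2$.

Their sum $\sigma^2_{\min}(\mu_i, N_i)$ is an effective infimum: a proposed
component narrower than this is physically impossible and gets posterior
density zero. Widths are therefore parameterized as multiples
$m_i = \sigma_i / \sigma_{\min}$ with the shifted-exponential prior

$$
\Pr(m) = \begin{cases} 0 & m < 1 \\
\lambda \, e^{-\lambda (m-1)} & m \ge 1, \end{cases}
$$

which permits broadening beyond the infimum (post-drift dispersion,
background) but disincentivizes it exponentially. Two erratum-style notes:
the Gaussian exponent is negative (a positive exponent diverges), and the
injection term is a variance (units s$^2$), so that the three terms add
consistently.

### Priors and likelihood

Centers carry a uniform prior on the sampling window $(a, b)$ — the span of
grid points above a baseline threshold (default 1% of the maximum);
components cannot sit outside the region of observed intensity. Amplitudes
are uniform on $[0, A_{\max}]$ with $A_{\max}$ the total observed count; a
*proper* amplitude prior is required for the model dimensions to be
comparable (an improper one would make the marginal likelihoods
incommensurable). The number of ions entering the Coulomb term is
$N_i = A_i \times$ `ions_per_count` (default 1, configurable because the
count-to-ion proportionality is instrument-specific).

The likelihood treats per-bin residuals as i.i.d. Gaussian with a single
scale $s$, making the sampler energy proportional to the residual sum of
squares — the familiar RMSE criterion embedded probabilistically. $s$ is
estimated as the median absolute deviation of the baseline region, floored
at $\sqrt{\max X}$: a clean synthetic ATD has an all-zero baseline (MAD
$= 0$), while Poisson counting noise at the peak scales as the square root
of the counts, so the floor is the natural counting-noise scale. A single
scale is deliberately simple; it under-weights the quiet flanks of strong
peaks relative to an exact Poisson likelihood.

## The three-stage pipeline

### 1. Equi-energy sampling (fixed $k$)

`run_equi_energy()` samples $\Pr(\Theta_k \mid k, X)$ with a ladder of
Metropolis chains at temperatures $T$ (geometric, default 5 levels, ratio
$\sqrt{10}$), run from hottest to coldest. Each level stores its states
binned into *energy rings* (boundaries from the 20/40/60/80% energy
quantiles of the hottest, pilot chain). A cooler chain proposes, with
probability `ee_jump_prob` (default 0.1), to adopt a stored state of the
next-hotter level from its current ring, accepted with the tempered ratio —
this is what lets low-temperature chains cross the energy barriers that
separate competing deconvolution solutions.

The local move is the joint two-step update: one uniformly chosen
component's $(A_i, \mu_i)$ is perturbed by a symmetric normal kernel, then
$m_i$ is redrawn from its prior and $\sigma_i^2$ recomputed from the
*updated* $(\mu_i, N_i)$. Jointly updating two blocks breaks global
detailed balance but preserves local balance (the forward and backward move
have equal proposal probability), which suffices for convergence. The
kernel also mixes in (probability 0.3, $k \ge 2$) a symmetric *amplitude
transfer* between two components that preserves their sum: overlapping
Gaussians make total intensity well determined but its allocation a long
flat ridge, and this is the move that walks it; without it the cold chains
take far longer to escape misallocated local optima.

Numerical choices: chains are initialized with centers at equal quantiles
of cumulative intensity and $m = 1.2$; proposal scales adapt toward 25–40%
acceptance during each level's burn-in (default 20%) and are frozen
afterwards; per-coordinate scales are re-estimated at each level from the
hotter chain's spread, because amplitudes (counts, $\sim 10^4$) and centers
(seconds, $\sim 10^{-6}$ posterior spread) differ by ten orders of
magnitude and one global multiplier cannot serve both; for generic targets
without re-estimation the local step grows as $\sqrt{T}$, matching the
width of the tempered target. Samples are stored center-sorted, the usual
identifiability convention for mixtures.

### 2. Bayesian sequential partitioning

`build_partition()` converts each fixed-$k$ sample set into a
piecewise-constant density that can be both *evaluated* and *sampled* —
the two operations the reversible-jump stage needs. The sample bounding
box (padded 5%, clamped at hard constraint boundaries such as $A \ge 0$
and $m \ge 1$) is split sequentially at dyadic midpoints of one coordinate
at a time. Candidate splits are scored by the multinomial–Dirichlet
marginal likelihood of the leaf counts (concentration 0.5 per leaf);
a particle system (default 100 particles) explores split sequences — leaf
chosen proportional to its count, coordinate by highest score gain with
ties to the lowest index — with systematic resampling when the importance
weights degenerate. The highest-weight partition is kept; leaf density is
$(\text{count}/n)/\text{volume}$. Zero-count leaves keep density zero
(no smoothing): the reversible-jump stage guards against them instead,
which avoids biasing the proposal toward regions no sample ever visited.
Degenerate coordinates (zero spread) are never split.

### 3. Reversible-jump MCMC over $k$

`run_rjmcmc()` runs a Markov chain on the union of the per-$k$ parameter
spaces. Proposed parameter vectors are drawn *whole* from the destination
dimension's partition tree (an independence proposal), so the usual
dimension-matching Jacobian is exactly 1 and the acceptance ratio is

$$
\frac{\pi(\Theta_{k'} \mid k', X)\,\Pr(k')\;q_k(\Theta_k)}
     {\pi(\Theta_k \mid k, X)\,\Pr(k)\;q_{k'}(\Theta_{k'})},
$$

with $q$ the tree densities. Within-dimension refresh moves (50% of steps)
redraw $\Theta_k$ from the current tree with the same ratio form. Because
the samplers work on the center-sorted (ordered) region, the
trans-dimensional target includes the $k!$ label-permutation multiplicity;
omitting it would bias the dimension posterior toward small $k$. The
dimension prior is flat by default — dimension inference rests on the error
of the model alone — with an optional geometric penalty. Proposals landing
in a zero-density leaf or violating a hard constraint are auto-rejected
(counted and reported, never divided by). Visit frequencies after burn-in
estimate $\Pr(k \mid X)$; the mean over the dimension posterior is the
headline "predicted number of components", and `consensus_solution()`
implements the convention that a mean falling between two integers
(fractional part in 0.3–0.7 by default) carries both neighboring models
forward.

The supervised dimension window is deliberately narrow: candidate ranges
wider than $[k, k+3]$ are rejected, reflecting how the method is used —
start from the lowest plausible dimension and extend upward.

## Downstream analyses

**Stepped-field CCS.** At fixed low field, arrival time is linear in the
inverse drift voltage, $t = L^2/(K V) + t_0$; `fit_stepped_field()`
recovers the mobility $K$ from the slope of an ordinary least squares fit
(with intercept: real instruments have a field-free transit time, so
absorbing it in $t_0$ is safe even when it is zero). A strongly nonlinear
trend (R$^2$ below a configurable 0.99) flags an incorrect deconvolution.
`mobility_to_ccs()` applies the Mason–Schamp equation
$\Omega = \frac{3 z e}{16 N}\sqrt{\frac{2\pi}{\mu k_B T}}\frac{1}{K}$ at
the measurement gas density $N$, reporting CCS in Å$^2$ together with the
reduced mobility $K_0$. CCS errors are $3\sigma$ confidence bounds
propagated from the slope covariance — the package standardizes on
$3\sigma$ throughout. `deconvolve_series()` enforces a constant component
count across voltages by majority vote over per-voltage modal dimensions
and links components by center rank, which is exact because arrival time
is monotone in $1/K$ at fixed voltage.

**CIU tracking.** Across a collision-voltage series, `track_ciu()` matches
components of adjacent voltages by greedy nearest-center assignment within
a tolerance; unmatched components end or start tracks, giving the
appearance/disappearance events and center shifts that make up an
unfolding fingerprint. Nearest-center matching is appropriate here because
activation shifts centers by much less than the peak spacing; across large
*drift*-voltage steps every center moves, and rank-based linking must be
used instead.

**Background flagging.** Components much wider than their own physics
infimum (default 3×) with small amplitude (default < 10% of the maximum)
are candidates for contaminating ion background sitting between real peaks
and can be omitted from CCS tables.

## The synthetic world

`sim_scenario()`/`simulate_atd()` generate validation data that obey the
package's own physics: component variances sit at `slack` × the broadening
infimum computed from the scenario's instrument configuration, intensities
are expected counts per bin with Poisson (default), Gaussian, or no noise,
and voltage series follow the stepped-field law with variances recomputed
per voltage. The default instrument block is a realistic low-pressure
helium drift tube — $L = 0.2505$ m, 400 Pa, 298 K, 150 µs injection pulse,
drift voltages of order 100–200 V — chosen once and used unchanged
throughout the tests; the default scenario (charge 7+, three components of
$6\text{–}10 \times 10^4$ ions, mobilities 0.057–0.075 m$^2$V$^{-1}$s$^{-1}$)
emulates a protein with a high charge state and several conformations,
with arrival times of 5–8 ms, peak widths of ~0.25 ms and peak
signal-to-noise around 60. A 200-point grid mirrors the data density of
time-of-flight-multiplexed drift instruments.

What the generator does **not** emulate: vendor file formats, mass
spectral dimensions, non-uniform fields (traveling-wave or trapped IMS
broadening physics is explicitly out of scope), drifts in instrument
conditions between voltage steps, and structured (non-Gaussian,
correlated) backgrounds — a green test therefore establishes correctness
of the inference machinery on data that satisfy the model's assumptions,
not robustness to instrument artifacts outside them.

## Known limitations

* At very high signal-to-noise the dimension posterior concentrates almost
  entirely on one $k$; with few accepted trans-dimensional jumps the chain
  is then effectively winner-takes-all, and distinguishing
  $\Pr(k) = 0.999$ from $1$ is beyond its resolution. Fractional mean
  dimensions are informative mainly in the noise regime of real data.
* The single Gaussian noise scale is a first-order stand-in for Poisson
  counting statistics.
* The BSP proposal is piecewise-uniform; in high dimensions a draw from
  even the correct leaf can have a poor likelihood, so refresh acceptance
  rates of a few percent are normal and chain lengths should be set
  accordingly.
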