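# imsdeconv

Bayesian deconvolution of multicomponent arrival time distributions
(ATDs) from drift-tube ion mobility spectrometry (DTIMS), for mass
spectrometrists and ion-mobility practitioners who need to know *how
many* conformational components an ATD contains — not just how to fit a
preset number of Gaussians — and to extract a collision cross section
(CCS) for each one.

## What it computes

An ATD is modelled as a mixture of `k` Gaussian components,

    M(t, Θ) = Σᵢ Aᵢ / (σᵢ √(2π)) · exp(−(t − μᵢ)² / (2σᵢ²)),

whose temporal variances are bounded below by drift-tube broadening
physics: injection (`t_Inj²/12`), diffusion (`2 k_B T/(z e ΔV) · t²`) and
Coulomb repulsion (`C_Coul (3Q/(4π ε₀ ΔV L))^{2/3} t²`, `Q = z e Nᵢ`).
Widths are sampled as multiples `m = σ/σ_min ≥ 1` of that infimum under a
shifted-exponential prior `λ e^{−λ(m−1)}`. Inference proceeds in three
stages:

1. **Equi-energy sampling** of the fixed-dimension posterior
   `Pr(Θ_k | k, X)` for each candidate `k` — a temperature ladder with
   equi-energy jumps that crosses the barriers separating competing
   deconvolution solutions;
2. **Bayesian sequential partitioning (BSP)** — each sample set is
   discretized into an evaluable, sampleable piecewise-constant density;
3. **Reversible-jump MCMC** across dimensions, using the BSP densities as
   independence proposals (Jacobian = 1), whose visit frequencies give
   `Pr(k | X)` and the mean predicted number of components.

Downstream, stepped-field series (`t = L²/(K·V) + t₀`) yield mobilities
from linear fits against `1/V`, converted to CCS via the Mason–Schamp
equation with 3σ errors; collision-induced unfolding (CIU) series are
tracked component-by-component across activation voltages.

## Worked example

Simulate a protein-like 7+ ion with three conformational components in a
helium drift tube, then deconvolve with candidate dimensions 2–5:

```r
library(imsdeconv)

scn <- sim_scenario(n_ions  = c(8e4, 1e5, 6e4),
                    mobility = c(0.075, 0.065, 0.057),  # m² V⁻¹ s⁻¹
                    charge = 7L)
sim <- simulate_atd(scn, seed = 1)          # Poisson counting noise
fit <- deconvolve_atd(sim$atd, k_range = 2:5, charge = 7L, seed = 1)
summary(fit)
```

```
Bayesian ATD deconvolution

Dimension posterior:
 k probability
 2           0
 3           1
 4           0
 5           0
mean dimension 3.000; modal k = 3

Components (modal k):
 component amplitude center_ms  sigma_ms  fraction
         1  79871.92  5.577884 0.2314596 0.3317419
         2 101454.25  6.436785 0.2872284 0.4213824
         3  59439.11  7.343973 0.2749370 0.2468758

residual RMSE: 29.7 counts per bin
```

The sampler identifies three components (the generating truth), recovers
their amplitudes (80 000 / 100 000 / 60 000 ions), arrival times and
widths, and the residual RMSE sits at the Poisson noise scale. A
stepped-field series turns per-voltage centers into mobilities and CCSs:

```r
ser <- simulate_voltage_series(scn, c(100, 120, 140, 160, 180, 200))
ccs_table(lapply(ser, `[[`, "truth"), c(100, 120, 140, 160, 180, 200),
          scn$cfg, charge = 7L, ion_mass = 12360)
```

```
  component     K           K0      CCS    CCS_error R2  fraction
1         1 0.075 0.0002713873 1382.620 6.798081e-13  1 0.3333333
2         2 0.065 0.0002352024 1595.330 7.909397e-13  1 0.4166667
3         3 0.057 0.0002062544 1819.236 8.872481e-13  1 0.2500000
```

Columns: mobility `K` (m² V⁻¹ s⁻¹), reduced mobility `K0`, CCS and its 3σ
error (Å²), the linear-fit `R²` (a value materially below 1 flags an
incorrect deconvolution), and the component's population fraction.

See the vignette (`vignettes/atd-deconvolution.Rmd`) for the model,
priors, sampler parametrization and the design decisions behind them.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — simulating the
three-component scenario at the given seed, running the full
equi-energy → BSP → reversible-jump deconvolution over `k = 2..5`,
printing the dimension posterior and component table, and extracting the
stepped-field CCS table for a six-voltage series — then writes the JSON
result object to `--out`.
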