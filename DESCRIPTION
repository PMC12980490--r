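Package: imsdeconv
Title: Bayesian Deconvolution of Drift-Tube Ion Mobility Arrival Time
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-constrained Bayesian deconvolution of multicomponent
    arrival time distributions (ATDs) from drift-tube ion mobility
    spectrometry. Models an ATD as a mixture of Gaussian components whose
    temporal variances are bounded below by injection, diffusion and
    Coulomb-repulsion broadening theory. Fixed-dimension posteriors are
    sampled with an equi-energy (tempered) sampler, discretized by
    Bayesian sequential partitioning, and combined in a reversible-jump
    MCMC stage that infers the number of components. Includes stepped-field
    collision cross section (CCS) extraction via the Mason-Schamp equation,
    collision-induced unfolding (CIU) component tracking, and a synthetic
    ATD generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
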