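# Shared synthetic scenarios: a protein-like high charge state with several
# conformational components, mirroring the package's stated validation world
# (helium drift tube, 0.2505 m, ~ms arrival times).

protein_scenario <- function(noise = "poisson", slack = 1,
                             n_ions = c(8e4, 1e5, 6e4),
                             mobility = c(0.075, 0.065, 0.057)) {
  sim_scenario(n_ions = n_ions, mobility = mobility, charge = 7L,
               cfg = instrument_config(), noise = noise, slack = slack)
}

two_comp_scenario <- function(noise = "none") {
  sim_scenario(n_ions = c(6e4, 9e4), mobility = c(0.072, 0.058),
               charge = 7L, noise = noise)
}

# fast ladder for unit tests (acceptance tests size their own)
test_ladder <- function(steps = 1200) ladder_config(steps_per_level = steps)

# CODATA constants redeclared independently for oracle arithmetic
KB <- 1.380649e-23
QE <- 1.602176634e-19
EPS0 <- 8.8541878128e-12
AMU <- 1.66053906660e-27
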