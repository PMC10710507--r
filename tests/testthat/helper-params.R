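# Canonical parameter sets used across the test files.
#
# "study" sets use the fitted values of the stopped-flow analysis this
# package models: overall K_D fixed at 6 nM, receptor 1 uM after mixing.

KD_STUDY <- 6e-9
P0_STUDY <- 1e-6

if_study_params <- function() {
  mechanism_params("IF", k_plus_from_kd(KD_STUDY, 0.6, 0.01, 1.1, "IF"),
                   k_minus = 0.6, k_e = 0.01, k_r = 1.1)
}

cs_study_params <- function() {
  mechanism_params("CS", k_plus_from_kd(KD_STUDY, 0.005, 1.2, 0.6, "CS"),
                   k_minus = 0.005, k_e = 1.2, k_r = 0.6)
}

# CS truth with a plausible unbound active state (k_r >= 9 k_e) for
# discrimination studies.
cs_plausible_params <- function() {
  mechanism_params("CS", k_plus_from_kd(KD_STUDY, 0.6, 0.1, 1.2, "CS"),
                   k_minus = 0.6, k_e = 0.1, k_r = 1.2)
}

# Random physical parameter set: log-uniform rates, concentrations within
# the nM-to-100-uM window. Assumes the caller seeds the RNG.
random_params <- function(model) {
  ks <- 10^stats::runif(4, -3, 3)
  mechanism_params(model, k_plus = ks[1] * 1e6, k_minus = ks[2],
                   k_e = ks[3], k_r = ks[4])
}

random_concentrations <- function() {
  10^stats::runif(2, -9, -4)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
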