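# Shared fixtures built in code.

cal42 <- trust_calibration(0.42)
cal40 <- trust_calibration(0.40)

# printed reference response-surface coefficients (b1..b5) of the cohort
# fits used for axis arithmetic checks: global cognition and WMH outcome
ref_surface_cognition <- c(b1 = -0.49, b2 = -0.03, b3 = 0.01, b4 = 0.00,
                           b5 = 0.00)
ref_surface_wmh <- c(b1 = -0.86, b2 = -1.42, b3 = 0.00, b4 = 0.01,
                     b5 = 0.01)

# small deterministic cohort for structural tests
small_cohort <- function(n = 60, seed = 101, ...) {
  generate_cohort(simulation_config(n_subjects = n, seed = seed, ...))
}

axis_estimate <- function(tests, what) {
  tests$estimate[tests$quantity == what]
}
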