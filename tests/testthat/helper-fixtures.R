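# default (calibrated) configuration used across tests
default_params <- function(...) model_params(...)

# random but valid velocity curves / parameter sets for property tests:
# perturb the default multiplicatively and reject curves that violate the
# positivity invariant on [0, 0.21]
random_params <- function() {
  repeat {
    fac <- exp(runif(7, log(0.5), log(2)))
    curve <- tryCatch(
      velocity_curve(1.89e-2 * fac[1], -3.98e-3 * fac[2],
                     2.25e-4 * fac[3], 0.5 * fac[4]),
      error = function(e) NULL)
    if (!is.null(curve)) break
  }
  model_params(curve, D_O = 2e-9 * fac[5], f = 0.65 * fac[6],
               k_c = 7.3e-10 * fac[7], O_am = runif(1, 0.05, 0.21))
}

random_feasible_density <- function(params) {
  runif(1, 0.01, 0.95) * max_feasible_density(params)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
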