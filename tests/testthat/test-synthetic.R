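test_that("velocity sampler returns exact parabola values without noise", {
  vc <- velocity_curve()
  d <- sample_velocity_measurements(vc, c(0, 0.1, 0.21))
  expect_identical(d$V, worm_speed(vc, c(0, 0.1, 0.21)))
  n1 <- noise_spec("additive-gaussian", sd = 2e-5, seed = 4)
  d1 <- sample_velocity_measurements(vc, c(0, 0.1, 0.21), n1, n_per_level = 5)
  d2 <- sample_velocity_measurements(vc, c(0, 0.1, 0.21), n1, n_per_level = 5)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 15L)
})

test_that("sample means of noisy velocity measurements obey the CLT", {
  vc <- velocity_curve()
  sdn <- 2e-5; n <- 50
  inside <- vapply(1:100, function(s) {
    d <- sample_velocity_measurements(
      vc, c(0.05, 0.10, 0.15, 0.20),
      noise_spec("additive-gaussian", sd = sdn, seed = s), n_per_level = n)
    means <- tapply(d$V, d$O, mean)
    truth <- worm_speed(vc, as.numeric(names(means)))
    mean(abs(means - truth) <= 3 * sdn / sqrt(n))
  }, numeric(1))
  expect_gte(mean(inside), 0.95)
})

test_that("oxygen relaxation matches the exponential solution", {
  f <- 0.65; O_am <- 0.21; O_0 <- 0.02
  tr <- simulate_oxygen_relaxation(f, O_am, O_0, dt = 0.001, T_end = 15)
  # approaches ambient (deficit down by e^{-f T})
  expect_lt(abs(tail(tr$O, 1) - O_am), 1e-4)
  # deficit half-life = ln 2 / f
  t_half <- log(2) / f
  i <- which.min(abs(tr$t - t_half))
  expect_rel_equal(O_am - tr$O[i], (O_am - O_0) / 2, 1e-3)
  # matches explicit Euler integration of dO/dt = f(O_am - O) to O(dt)
  dt <- 0.001
  O_euler <- Reduce(function(O, .) O + dt * f * (O_am - O),
                    seq_len(nrow(tr) - 1), accumulate = TRUE, init = O_0)
  expect_lt(max(abs(tr$O - O_euler)), 5 * dt)
})

test_that("run-and-tumble walkers behave ballistically without turns and diffusively with", {
  V <- 2e-4
  straight <- simulate_run_and_tumble(V, 0, T_end = 10, dt = 0.1,
                                      n_walkers = 10, seed = 2)
  final <- straight[straight$t == 10, ]
  expect_equal(sqrt(final$x^2 + final$y^2), rep(V * 10, 10), tolerance = 1e-9)
  # ensemble MSD slope gives D = V^2/(2 tau) within 10%
  tau <- 0.5
  traj <- simulate_run_and_tumble(V, tau, T_end = 200 / tau, dt = 0.02,
                                  n_walkers = 500, seed = 5)
  D_hat <- estimate_turn_rate(traj, V, window = c(40, 200))$estimates$D
  expect_rel_equal(D_hat, V^2 / (2 * tau), 0.10)
  # determinism
  a <- simulate_run_and_tumble(V, tau, T_end = 5, dt = 0.05, n_walkers = 5,
                               seed = 9)
  b <- simulate_run_and_tumble(V, tau, T_end = 5, dt = 0.05, n_walkers = 5,
                               seed = 9)
  expect_identical(a, b)
  expect_error(simulate_run_and_tumble(V, tau, 10, dt = 1), "dt")
})

test_that("pattern fixtures are classified as their own label across seeds", {
  g <- grid2d(N = 64, L = 0.02)
  for (lab in c("uniform", "dots", "stripes", "holes")) {
    labs <- vapply(1:25, function(s) {
      classify_pattern(make_pattern_fixture(lab, g, 0.004, seed = s))
    }, character(1))
    expect_true(all(labs == lab))
  }
  expect_error(make_pattern_fixture("dots", g, wavelength = 0.01), "L/3")
})

test_that("fixture spectra peak at the construction wavelength", {
  g <- grid2d(N = 128, L = 0.02)
  dk <- 2 * pi / g$L
  sp <- structure_spectrum(make_pattern_fixture("stripes", g, 0.004), g)
  expect_lt(abs(sp$k_peak - 2 * pi / 0.004), dk + 1e-9)
})

test_that("equilibrium dataset integrates to the closed-form balance", {
  p <- default_params()
  W <- c(0, 2e7, 5e7, 8e7)
  d <- make_equilibrium_dataset(p, W)
  expect_equal(d$O_eq[1], p$O_am, tolerance = 1e-8)
  closed <- equilibrium_oxygen(p, W)$O_eq
  expect_lt(max(abs(d$O_eq - closed)), 1e-6)
  expect_true(all(diff(d$O_eq) < 0))
  expect_error(make_equilibrium_dataset(p, 1e9), "infeasible")
})
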