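test_that("velocity-curve fit is exact on noiseless samples and errors when rank-deficient", {
  vc <- velocity_curve()
  d <- sample_velocity_measurements(vc, seq(0, 0.21, length.out = 11))
  fit <- fit_velocity_curve(d)
  expect_rel_equal(fit$estimates$a, vc$a, 1e-10)
  expect_rel_equal(fit$estimates$b, vc$b, 1e-10)
  expect_rel_equal(fit$estimates$c, vc$c, 1e-10)
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b", "c"))
  expect_identical(nrow(glance(fit)), 1L)
  two <- data.frame(O = c(0.1, 0.1, 0.2), V = c(1e-4, 1.1e-4, 2e-4))
  expect_error(fit_velocity_curve(two), "3 distinct")
})

test_that("velocity-fit coefficients are within 3 SE of truth in >= 95% of replicates", {
  vc <- velocity_curve()
  O_grid <- seq(0, 0.21, length.out = 10)
  hits <- vapply(1:200, function(s) {
    d <- sample_velocity_measurements(
      vc, O_grid, noise_spec("additive-gaussian", sd = 1e-5, seed = s),
      n_per_level = 20)
    fit <- fit_velocity_curve(d)
    all(abs(fit$estimates$a - vc$a) <= 3 * fit$std_errors$a,
        abs(fit$estimates$b - vc$b) <= 3 * fit$std_errors$b,
        abs(fit$estimates$c - vc$c) <= 3 * fit$std_errors$c)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("penetration rate is recovered from relaxation traces", {
  f_true <- 0.65
  tr <- simulate_oxygen_relaxation(f_true, 0.21, 0.05, dt = 0.01, T_end = 20)
  fit <- estimate_penetration_rate(tr, O_am = 0.21)
  expect_rel_equal(fit$estimates$f, f_true, 1e-9)
  # f = 0: flat trace, flagged non-identifiable
  flat <- simulate_oxygen_relaxation(0, 0.21, 0.05, dt = 0.1, T_end = 20)
  fit0 <- estimate_penetration_rate(flat, O_am = 0.21)
  expect_true("non_identifiable" %in% fit0$flags)
  expect_false(fit0$converged)
  # trace touching ambient is an error (log of zero)
  expect_error(
    estimate_penetration_rate(data.frame(t = 0:3, O = c(0.1, 0.2, 0.21, 0.21)),
                              O_am = 0.21), "touches")
  # noisy recovery within 2% median over 100 seeds
  errs <- vapply(1:100, function(s) {
    tr <- simulate_oxygen_relaxation(
      f_true, 0.21, 0.05, dt = 0.01, T_end = 20,
      noise_spec("additive-gaussian", sd = 1e-3, seed = s))
    abs(estimate_penetration_rate(tr, 0.21)$estimates$f - f_true) / f_true
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("consumption coefficient is recovered from equilibrium pairs", {
  p <- default_params()
  W <- seq(1e7, 9e7, length.out = 5)
  exact <- equilibrium_oxygen(p, W)
  fit <- estimate_consumption_rate(data.frame(W = W, O_eq = exact$O_eq),
                                   f = p$f, O_am = p$O_am)
  expect_rel_equal(fit$estimates$k_c, p$k_c, 1e-12)
  # pairs generated by time integration of the uniform ODE, not closed form
  ode_data <- make_equilibrium_dataset(p, W)
  fit2 <- estimate_consumption_rate(ode_data, f = p$f, O_am = p$O_am)
  expect_rel_equal(fit2$estimates$k_c, p$k_c, 1e-3)
  expect_error(
    estimate_consumption_rate(data.frame(W = c(5e7, 5e7), O_eq = c(0.1, 0.1)),
                              f = p$f, O_am = p$O_am), "distinct")
})

test_that("turn rate is recovered from run-and-tumble trajectories", {
  tau <- 0.5; V <- 2e-4
  traj <- simulate_run_and_tumble(V, tau, T_end = 200, dt = 0.01,
                                  n_walkers = 500, seed = 42)
  fit <- estimate_turn_rate(traj, V)
  expect_rel_equal(fit$estimates$tau, tau, 0.10)
  # turn-free walkers are ballistic: flagged, not silently trusted
  straight <- simulate_run_and_tumble(V, 0, T_end = 50, dt = 0.05,
                                      n_walkers = 50, seed = 1)
  fit0 <- estimate_turn_rate(straight, V, window = c(5, 25))
  expect_true(any(c("superdiffusive", "short_trajectory") %in% fit0$flags))
})

test_that("doubling speed quadruples the fitted diffusion at fixed tau", {
  # same seed -> identical turn sequence, so D scales exactly as V^2
  t1 <- simulate_run_and_tumble(2e-4, 0.5, T_end = 100, dt = 0.02,
                                n_walkers = 100, seed = 7)
  t2 <- simulate_run_and_tumble(4e-4, 0.5, T_end = 100, dt = 0.02,
                                n_walkers = 100, seed = 7)
  D1 <- estimate_turn_rate(t1, 2e-4, window = c(20, 50))$estimates$D
  D2 <- estimate_turn_rate(t2, 4e-4, window = c(20, 50))$estimates$D
  expect_rel_equal(D2, 4 * D1, 1e-10)
})

test_that("oxygen diffusion is recovered from a spreading bump within 1%", {
  D_true <- 2e-9
  g <- grid2d(N = 256, L = 0.02)
  tr <- simulate_diffusion_bump(D_true, g, sigma0 = 5e-4, t_end = 50,
                                save_every = 5)
  fit <- estimate_oxygen_diffusion(tr)
  expect_rel_equal(fit$estimates$D_O, D_true, 0.01)
  # both axes agree (isotropy)
  expect_rel_equal(fit$estimates$D_x, fit$estimates$D_y, 0.02)
  # a bump wider than the wrap-safe limit is rejected
  wide <- simulate_diffusion_bump(D_true, grid2d(N = 64, L = 0.02),
                                  sigma0 = 4e-3, t_end = 5, save_every = 5)
  expect_error(estimate_oxygen_diffusion(wide), "wide")
})

test_that("diffusion estimate converges under grid refinement", {
  D_true <- 2e-9
  est <- vapply(c(128, 256), function(N) {
    tr <- simulate_diffusion_bump(D_true, grid2d(N = N, L = 0.02),
                                  sigma0 = 5e-4, t_end = 30, save_every = 10)
    estimate_oxygen_diffusion(tr)$estimates$D_O
  }, numeric(1))
  expect_lt(abs(est[2] - est[1]) / est[1], 0.005)
})
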