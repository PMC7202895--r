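test_that("initialisation is seeded, mean-exact, and uniform when noiseless", {
  p <- default_params()
  g <- grid2d(N = 32)
  s0 <- initialize_state(p, g, 6e7, noise_amplitude = 0)
  expect_true(all(s0$W == 6e7))
  expect_true(all(s0$O == equilibrium_oxygen(p, 6e7)$O_eq))
  s1 <- initialize_state(p, g, 6e7, seed = 11)
  s2 <- initialize_state(p, g, 6e7, seed = 11)
  expect_identical(s1$W, s2$W)
  s3 <- initialize_state(p, g, 6e7, seed = 12)
  expect_false(identical(s1$W, s3$W))
  # noise mean is removed, so the field mean is W_eq to rounding
  expect_rel_equal(mean(s1$W), 6e7, 1e-12)
  expect_error(initialize_state(p, g, max_feasible_density(p) * 2),
               "infeasible")
})

test_that("uniform feasible states are fixed points and W=0 is stationary", {
  p <- default_params()
  g <- grid2d(N = 32)
  s0 <- initialize_state(p, g, 6e7, noise_amplitude = 0)
  s <- step_state(s0, p, dt = 0.1, nsteps = 200)
  expect_lt(max(abs(s$W - 6e7)) / 6e7, 1e-12)
  expect_lt(max(abs(s$O - s0$O[1, 1])), 1e-12)
  # worm-free saturated state
  empty <- initialize_state(p, g, 0, noise_amplitude = 0)
  s <- step_state(empty, p, dt = 0.1, nsteps = 100)
  expect_true(all(s$W == 0))
  expect_lt(max(abs(s$O - p$O_am)), 1e-14)
})

test_that("worm mass is conserved and oxygen stays within [0, O_am]", {
  p <- default_params()
  g <- grid2d(N = 32)
  s0 <- initialize_state(p, g, 6e7, noise_amplitude = 0.01, seed = 3)
  mass0 <- sum(s0$W)
  s <- step_state(s0, p, dt = 0.15, nsteps = 1e4)
  expect_lt(abs(sum(s$W) - mass0) / mass0, 1e-8)
  expect_gte(min(s$W), 0)
  expect_gte(min(s$O), 0)
  expect_lte(max(s$O), p$O_am)
})

test_that("a single unstable eigenmode grows at the predicted rate", {
  # one in-band mode as a fast sanity check; the multi-mode in/out-of-band
  # comparison lives in the acceptance suite
  p <- default_params(L = 0.01)
  g <- grid2d(N = 128, L = 0.01)
  ini <- initialize_mode(p, g, 4e7, mode = 5, amplitude = 1e-4)
  dt <- cfl_dt(p, g)
  x <- (seq_len(g$N) - 1) * g$dx
  sn <- sin(ini$k * x)
  proj <- function(st) sum((rowMeans(st$W) - 4e7) * sn) / sum(sn^2) / 4e7
  st <- ini$state
  ts <- 0; amps <- proj(st)
  for (i in 1:5) {
    st <- step_state(st, p, dt, round(6 / dt))
    ts <- c(ts, st$t); amps <- c(amps, proj(st))
  }
  rate <- unname(coef(lm(log(abs(amps)) ~ ts))[2])
  expect_rel_equal(rate, ini$lambda, 0.05)
})

test_that("halving dt leaves the final pattern essentially unchanged", {
  p <- default_params()
  g <- grid2d(N = 64)
  dt <- cfl_dt(p, g)
  dt <- 60 / ceiling(60 / dt)
  t1 <- run_simulation(p, g, 6e7, t_end = 60, save_every = 60,
                       seed = 5, dt = dt)
  t2 <- run_simulation(p, g, 6e7, t_end = 60, save_every = 60,
                       seed = 5, dt = dt / 2)
  W1 <- t1$states[[2]]$W; W2 <- t2$states[[2]]$W
  rms <- sqrt(mean((W1 - W2)^2)) / mean(W1)
  expect_lt(rms, 0.01)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- default_params()
  g <- grid2d(N = 32)
  a <- run_simulation(p, g, 5e7, t_end = 30, save_every = 30, seed = 9)
  b <- run_simulation(p, g, 5e7, t_end = 30, save_every = 30, seed = 9)
  expect_identical(a$states[[2]]$W, b$states[[2]]$W)
  expect_identical(a$states[[2]]$O, b$states[[2]]$O)
})

test_that("a time step far above the CFL bound aborts with a diagnostic", {
  p <- default_params()
  g <- grid2d(N = 64)
  s0 <- initialize_state(p, g, 6e7, seed = 1)
  expect_error(step_state(s0, p, dt = 50 * cfl_dt(p, g), nsteps = 500),
               "CFL")
})

test_that("an unstable density forms a non-uniform pattern by 10 model-minutes", {
  p <- default_params()
  g <- grid2d(N = 64)
  tr <- run_simulation(p, g, 6e7, t_end = 600, save_every = 600, seed = 2)
  expect_false(classify_pattern(tr$states[[2]]$W) == "uniform")
  # and a stable density decays back to uniform
  tr0 <- run_simulation(p, g, 2e7, t_end = 600, save_every = 600, seed = 2)
  expect_identical(classify_pattern(tr0$states[[2]]$W), "uniform")
})
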