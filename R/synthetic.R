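#' Noise specification for synthetic generators
#'
#' @param kind `"none"` or `"additive-gaussian"`.
#' @param sd Noise standard deviation, in the units of the signal.
#' @param seed Integer seed for the generator.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "additive-gaussian"), sd = 0,
                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0)
  if (kind == "additive-gaussian" && sd == 0) kind <- "none"
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$kind == "none") return(x)
  set.seed(noise$seed)
  x + rnorm(length(x), 0, noise$sd)
}

#' Synthetic speed-versus-oxygen measurements
#'
#' Emulates motility assays: the true parabolic curve is sampled at a grid
#' of ambient oxygen levels, with optional additive Gaussian measurement
#' noise, `n_per_level` replicates per level.
#'
#' @param curve A [velocity_curve()].
#' @param O_grid Oxygen fractions within \[0, 0.3\].
#' @param noise A [noise_spec()] (sd in m/s).
#' @param n_per_level Replicates per oxygen level.
#' @return A tibble with columns `O`, `V`.
#' @export
sample_velocity_measurements <- function(curve, O_grid,
                                         noise = noise_spec(),
                                         n_per_level = 1L) {
  stopifnot(all(O_grid >= 0), all(O_grid <= 0.3), n_per_level >= 1)
  O <- rep(O_grid, each = n_per_level)
  V <- worm_speed(curve, O)
  tibble::tibble(O = O, V = apply_noise(V, noise))
}

#' Synthetic worm-free oxygen relaxation trace
#'
#' With no consumers the surface oxygen relaxes exponentially to ambient:
#' \eqn{O(t) = O_{am} - (O_{am} - O_0)e^{-ft}}; the exact solution is
#' sampled at interval `dt`, with optional additive noise.
#'
#' @param f Penetration rate, 1/s.
#' @param O_am Ambient oxygen fraction.
#' @param O_0 Initial oxygen fraction in \[0, O_am\].
#' @param dt Sampling interval, s.
#' @param T_end Trace duration, s.
#' @param noise A [noise_spec()] (sd in oxygen fraction).
#' @return A tibble with columns `t`, `O`.
#' @export
simulate_oxygen_relaxation <- function(f, O_am, O_0, dt, T_end,
                                       noise = noise_spec()) {
  stopifnot(f >= 0, O_0 >= 0, O_0 <= O_am, dt > 0, T_end > dt)
  t <- seq(0, T_end, by = dt)
  O <- O_am - (O_am - O_0) * exp(-f * t)
  tibble::tibble(t = t, O = apply_noise(O, noise))
}

#' Simulate 2-D constant-speed run-and-tumble trajectories
#'
#' Each walker moves at speed `V` and reorients to a uniformly random
#' direction at Poisson rate `tau`. Turns are drawn per step with
#' probability `1 - exp(-tau dt)` (the exact Poisson probability of at
#' least one event per step; with a uniform tumble kernel the end-of-step
#' direction distribution is exact, and the within-step position error is
#' O(dt)). `dt <= 0.1/tau` is enforced.
#'
#' @param V Speed, m/s.
#' @param tau Direction-change rate, 1/s.
#' @param T_end Duration, s.
#' @param dt Integration step, s.
#' @param n_walkers Number of independent walkers.
#' @param seed Integer seed.
#' @param record_every Record positions every this many steps (default
#'   chosen to keep about 200 frames).
#' @return A tibble with columns `walker`, `t`, `x`, `y` (m).
#' @export
simulate_run_and_tumble <- function(V, tau, T_end, dt, n_walkers = 500L,
                                    seed = 1L, record_every = NULL) {
  stopifnot(V >= 0, tau >= 0, T_end > 0, dt > 0, n_walkers >= 1)
  if (tau > 0 && dt > 0.1 / tau) {
    stop("`dt` must satisfy dt <= 0.1/tau to resolve turning events",
         call. = FALSE)
  }
  nsteps <- round(T_end / dt)
  if (is.null(record_every)) record_every <- max(1L, round(nsteps / 200))
  set.seed(seed)
  theta <- runif(n_walkers, 0, 2 * pi)
  x <- y <- numeric(n_walkers)
  p_turn <- 1 - exp(-tau * dt)
  n_rec <- floor(nsteps / record_every) + 1L
  xs <- matrix(0, n_rec, n_walkers)
  ys <- matrix(0, n_rec, n_walkers)
  ts <- numeric(n_rec)
  rec <- 1L
  for (s in seq_len(nsteps)) {
    if (p_turn > 0) {
      turn <- runif(n_walkers) < p_turn
      n_turn <- sum(turn)
      if (n_turn > 0) theta[turn] <- runif(n_turn, 0, 2 * pi)
    }
    x <- x + V * cos(theta) * dt
    y <- y + V * sin(theta) * dt
    if (s %% record_every == 0) {
      rec <- rec + 1L
      xs[rec, ] <- x
      ys[rec, ] <- y
      ts[rec] <- s * dt
    }
  }
  tibble::tibble(walker = rep(seq_len(n_walkers), each = n_rec),
                 t = rep(ts, n_walkers),
                 x = as.vector(xs), y = as.vector(ys))
}

# sum of periodic (minimum-image) Gaussian bumps at given centres
bump_field <- function(grid, centers, sigma) {
  N <- grid$N
  xc <- (seq_len(N) - 0.5) * grid$dx
  field <- matrix(0, N, N)
  for (i in seq_len(nrow(centers))) {
    dx_ <- abs(xc - centers[i, 1])
    dx_ <- pmin(dx_, grid$L - dx_)
    dy_ <- abs(xc - centers[i, 2])
    dy_ <- pmin(dy_, grid$L - dy_)
    field <- field + outer(exp(-dx_^2 / (2 * sigma^2)),
                           exp(-dy_^2 / (2 * sigma^2)))
  }
  field
}

#' Labelled synthetic pattern fixtures
#'
#' Constructs fields with known morphology for testing the classifier and
#' the structure spectrum: `uniform` is a constant with tiny noise, `dots`
#' a periodic lattice of Gaussian bumps at the given spacing (with seeded
#' sub-cell jitter), `holes` the inverted lattice, `stripes` a sinusoid.
#' Modulation amplitude is half the field mean.
#'
#' @param label One of `"uniform"`, `"dots"`, `"stripes"`, `"holes"`.
#' @param grid A [grid2d()].
#' @param wavelength Pattern spacing, m; must be below `L/3`.
#' @param seed Integer seed (jitters bump positions; never the label).
#' @param mean_level Field mean (default 1).
#' @return A numeric `N x N` matrix.
#' @export
make_pattern_fixture <- function(label, grid, wavelength, seed = 1L,
                                 mean_level = 1) {
  label <- match.arg(label, c("uniform", "dots", "stripes", "holes"))
  stopifnot(inherits(grid, "grid2d"), wavelength > 0, mean_level > 0)
  if (wavelength >= grid$L / 3) {
    stop("`wavelength` must be below L/3 for an unambiguous fixture",
         call. = FALSE)
  }
  N <- grid$N
  set.seed(seed)
  if (label == "uniform") {
    return(matrix(mean_level * (1 + 1e-3 * runif(N * N, -1, 1)), N, N))
  }
  if (label == "stripes") {
    xc <- (seq_len(N) - 0.5) * grid$dx
    n_waves <- max(3, round(grid$L / wavelength))
    s <- sin(2 * pi * n_waves * xc / grid$L)
    return(matrix(rep(mean_level * (1 + 0.5 * s), N), N, N))
  }
  # dots / holes: jittered lattice of bumps, spacing = wavelength
  n_side <- max(3, round(grid$L / wavelength))
  spacing <- grid$L / n_side
  base <- (seq_len(n_side) - 0.5) * spacing
  centers <- as.matrix(expand.grid(x = base, y = base))
  centers <- centers + matrix(runif(length(centers), -0.1, 0.1) * spacing,
                              ncol = 2)
  bumps <- bump_field(grid, centers %% grid$L, sigma = spacing / 6)
  bumps <- bumps / max(bumps)
  mod <- bumps - mean(bumps)
  mod <- mod / max(abs(mod))
  if (label == "holes") mod <- -mod
  field <- mean_level * (1 + 0.5 * mod)
  pmax(field, 0)
}

#' Equilibrium (density, oxygen) pairs by ODE integration
#'
#' For each density the spatially uniform oxygen equation
#' \eqn{dO/dt = f(O_{am} - O) - k_c W} is integrated to steady state (time
#' horizon `30/f`), rather than evaluated in closed form, so the dataset
#' genuinely exercises [estimate_consumption_rate()].
#'
#' @param params A [model_params()].
#' @param W_list Worm densities, worms/m^2 (all feasible).
#' @return A tibble with columns `W`, `O_eq`.
#' @export
make_equilibrium_dataset <- function(params, W_list) {
  stopifnot(all(W_list >= 0))
  if (any(W_list > max_feasible_density(params))) {
    stop("infeasible density in `W_list` (O_eq would be negative)",
         call. = FALSE)
  }
  O_eq <- vapply(W_list, function(W) {
    sol <- deSolve::ode(y = c(O = params$O_am), times = c(0, 30 / params$f),
                        func = function(t, y, p) {
                          list(params$f * (params$O_am - y[1]) -
                                 params$k_c * W)
                        }, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    unname(sol[nrow(sol), "O"])
  }, numeric(1))
  tibble::tibble(W = W_list, O_eq = O_eq)
}

#' Pure-diffusion oxygen bump trajectory
#'
#' Evolves a compact Gaussian oxygen bump on the periodic grid with
#' diffusion only (no penetration, no worms), using the same conservative
#' stepper as the full model. Input for [estimate_oxygen_diffusion()].
#'
#' @param D_O Diffusion coefficient, m^2/s.
#' @param grid A [grid2d()].
#' @param sigma0 Initial bump standard deviation, m.
#' @param t_end Duration, s.
#' @param save_every Snapshot interval, s.
#' @param amplitude Peak oxygen fraction of the bump (default 0.1).
#' @param dt Optional explicit time step, s.
#' @return An `aeropattern_trajectory` whose states carry the oxygen field
#'   (worm field identically zero).
#' @export
simulate_diffusion_bump <- function(D_O, grid, sigma0 = 5e-4, t_end = 50,
                                    save_every = 5, amplitude = 0.1,
                                    dt = NULL) {
  stopifnot(D_O > 0, inherits(grid, "grid2d"), sigma0 > 0)
  N <- grid$N
  xc <- (seq_len(N) - 0.5) * grid$dx
  ctr <- grid$L / 2
  O <- amplitude * outer(exp(-(xc - ctr)^2 / (2 * sigma0^2)),
                         exp(-(xc - ctr)^2 / (2 * sigma0^2)))
  W <- matrix(0, N, N)
  if (is.null(dt)) {
    dt_max <- 0.9 * grid$dx^2 / (4 * D_O)
    dt <- save_every / ceiling(save_every / dt_max)
  }
  n_per_save <- round(save_every / dt)
  n_saves <- floor(t_end / save_every + 1e-9)
  state <- new_field_state(0, W, O, grid)
  states <- vector("list", n_saves + 1L)
  states[[1L]] <- state
  for (i in seq_len(n_saves)) {
    out <- pde_steps_cpp(state$W, state$O, as.integer(n_per_save), dt,
                         grid$dx, 0, 0, 0, 1, D_O, 0, 0, 1, 1e6)
    state <- new_field_state(state$t + n_per_save * dt, out$W, out$O, grid)
    states[[i + 1L]] <- state
  }
  structure(list(states = states,
                 times = vapply(states, function(s) s$t, numeric(1)),
                 params = NULL, grid = grid,
                 config = list(D_O = D_O, sigma0 = sigma0, dt = dt,
                               t_end = t_end, save_every = save_every),
                 clamp_log = list(clamp_W_events = 0, clamp_O_events = 0,
                                  clamped_mass = 0)),
            class = "aeropattern_trajectory")
}
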