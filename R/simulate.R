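#' Periodic square simulation grid
#'
#' @param N Cells per side (>= 16).
#' @param L Domain side length in metres (default 2 cm).
#' @return An object of class `grid2d` with fields `N`, `L`, `dx = L/N`.
#' @export
grid2d <- function(N = 256, L = 0.02) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 16, N == round(N),
            is.numeric(L), L > 0)
  structure(list(N = as.integer(N), L = L, dx = L / N), class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d cells, L = %.3g m, dx = %.3g m\n",
              x$N, x$N, x$L, x$dx))
  invisible(x)
}

#' Largest stable explicit time step for the simulator
#'
#' The explicit Euler scheme is diffusion-limited:
#' `dt <= 0.9 dx^2 / (4 max(D_W, D_O))` with the worm diffusivity maximised
#' over the reachable oxygen range, and additionally `dt <= 0.1/f` so the
#' penetration relaxation is resolved.
#'
#' @param params A [model_params()].
#' @param grid A [grid2d()].
#' @return Time step in seconds.
#' @export
cfl_dt <- function(params, grid) {
  O <- seq(0, params$O_am, length.out = 64)
  D_max <- max(worm_diffusivity(params$curve, O), params$D_O)
  min(0.9 * grid$dx^2 / (4 * D_max), 0.1 / params$f)
}

new_field_state <- function(t, W, O, grid) {
  structure(list(t = t, W = W, O = O, grid = grid), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %.5g s, %d x %d cells\n", x$t,
              nrow(x$W), ncol(x$W)))
  cat(sprintf("  W: mean %.4g worms/m^2 [%.3g, %.3g]\n",
              mean(x$W), min(x$W), max(x$W)))
  cat(sprintf("  O: mean %.4g [%.4g, %.4g]\n", mean(x$O), min(x$O), max(x$O)))
  invisible(x)
}

#' Initialise a noisy uniform state
#'
#' Worms are uniformly distributed with multiplicative noise,
#' `W = W_eq (1 + amplitude * eta)` with `eta` i.i.d. uniform on \[-1, 1\]
#' and its sample mean removed, so `mean(W)` equals `W_eq` exactly; oxygen
#' starts at the corresponding equilibrium value.
#'
#' @param params A [model_params()].
#' @param grid A [grid2d()].
#' @param W_eq Uniform worm density, worms/m^2 (must be feasible).
#' @param noise_amplitude Relative noise amplitude (default 0.01).
#' @param seed Integer seed; identical seeds give identical states.
#' @return A `field_state`.
#' @export
initialize_state <- function(params, grid, W_eq, noise_amplitude = 0.01,
                             seed = 1L) {
  stopifnot(inherits(grid, "grid2d"), W_eq >= 0, noise_amplitude >= 0)
  eq <- equilibrium_oxygen(params, W_eq)
  N <- grid$N
  if (noise_amplitude > 0) {
    set.seed(seed)
    eta <- matrix(runif(N * N, -1, 1), N, N)
    eta <- eta - mean(eta)
  } else {
    eta <- matrix(0, N, N)
  }
  W <- W_eq * (1 + noise_amplitude * eta)
  O <- matrix(eq$O_eq, N, N)
  new_field_state(0, W, O, grid)
}

#' Initialise a single-mode sinusoidal perturbation
#'
#' Seeds the linearised system's eigenmode at domain harmonic `mode`
#' (wavenumber `k = 2 pi mode / L`) along the x axis, with both the
#' density and oxygen components set along the slow (largest-eigenvalue)
#' eigenvector so the subsequent amplitude evolution is a clean
#' single-exponential. Used to verify the simulator against the closed-form
#' dispersion relation.
#'
#' @inheritParams initialize_state
#' @param mode Integer harmonic along x (>= 1).
#' @param amplitude Relative density perturbation amplitude (default 1e-4).
#' @return A list: `state` (`field_state`), `k` (1/m), `lambda` (predicted
#'   growth rate, 1/s).
#' @export
initialize_mode <- function(params, grid, W_eq, mode, amplitude = 1e-4) {
  stopifnot(mode >= 1, mode == round(mode))
  eq <- equilibrium_oxygen(params, W_eq)
  k <- 2 * pi * mode / grid$L
  J <- jacobian_at_k(params, W_eq, k)
  ei <- eigen(J)
  i_slow <- which.max(Re(ei$values))
  lambda <- ei$values[i_slow]
  v <- ei$vectors[, i_slow]
  if (abs(Im(lambda)) > 1e-12 * abs(Re(lambda))) {
    warning("complex growth rate; perturbation uses the real part of the eigenvector")
  }
  v <- Re(v) / Re(v)[1]
  N <- grid$N
  x <- (seq_len(N) - 1) * grid$dx
  s <- sin(k * x)
  dW <- amplitude * W_eq
  W <- matrix(rep(W_eq + dW * s, N), N, N)
  O <- matrix(rep(eq$O_eq + dW * v[2] * s, N), N, N)
  list(state = new_field_state(0, W, O, grid), k = k, lambda = Re(lambda))
}

#' Advance a field state by explicit Euler steps
#'
#' Conservative finite-volume update on the periodic grid (see [cfl_dt()]
#' for the stability bound): worm fluxes `D_W(O) grad W + beta(O) W grad O`
#' evaluated at cell faces with arithmetically averaged oxygen, oxygen
#' updated by diffusion, air penetration and consumption. Worm density is
#' clamped at zero (with mass redistributed proportionally) and oxygen to
#' `[0, O_am]`; clamp events are counted on the returned state.
#'
#' @param state A `field_state`.
#' @param params A [model_params()].
#' @param dt Time step, s. Must respect [cfl_dt()].
#' @param nsteps Number of steps to take (default 1).
#' @return The advanced `field_state` with attributes `clamp_W_events`,
#'   `clamp_O_events`, `clamped_mass`.
#' @export
step_state <- function(state, params, dt, nsteps = 1L) {
  stopifnot(inherits(state, "field_state"), dt > 0, nsteps >= 1)
  cv <- params$curve
  out <- pde_steps_cpp(state$W, state$O, as.integer(nsteps), dt,
                       state$grid$dx, cv$a, cv$b, cv$c, cv$tau,
                       params$D_O, params$f, params$k_c, params$O_am,
                       1e6)
  if (out$aborted) {
    stop(sprintf(paste0("simulation diverged at t = %.4g s (runaway worm ",
                        "density or macroscopic positivity clamping); ",
                        "dt = %.4g s likely violates the CFL ",
                        "bound dt <= %.4g s from cfl_dt()"),
                 state$t + out$steps_done * dt, dt,
                 cfl_dt(params, state$grid)),
         call. = FALSE)
  }
  st <- new_field_state(state$t + nsteps * dt, out$W, out$O, state$grid)
  attr(st, "clamp_W_events") <- out$clamp_W_events
  attr(st, "clamp_O_events") <- out$clamp_O_events
  attr(st, "clamped_mass") <- out$clamped_mass
  st
}

#' Run a pattern-formation simulation
#'
#' Integrates the coupled equations from a noisy uniform state, saving
#' snapshots every `save_every` seconds of model time. The time step is the
#' largest stable step that divides `save_every` exactly unless `dt` is
#' given.
#'
#' @inheritParams initialize_state
#' @param t_end Total model time, s.
#' @param save_every Snapshot interval, s.
#' @param dt Optional explicit time step, s.
#' @param out_dir Optional directory; when given, snapshots and a JSON run
#'   manifest are written there.
#' @return An `aeropattern_trajectory`: list with `states` (list of
#'   `field_state`, including t = 0), `times`, `params`, `grid`, `config`,
#'   and clamp-event log.
#' @examples
#' \donttest{
#' p <- model_params()
#' g <- grid2d(N = 64, L = 0.02)
#' tr <- run_simulation(p, g, W_eq = 6e7, t_end = 60, save_every = 30, seed = 2)
#' classify_pattern(tr$states[[length(tr$states)]]$W)
#' }
#' @export
run_simulation <- function(params, grid, W_eq, t_end, save_every,
                           noise_amplitude = 0.01, seed = 1L, dt = NULL,
                           out_dir = NULL) {
  stopifnot(t_end > 0, save_every > 0, save_every <= t_end)
  if (is.null(dt)) {
    dt_max <- cfl_dt(params, grid)
    dt <- save_every / ceiling(save_every / dt_max)
  }
  n_per_save <- round(save_every / dt)
  if (abs(n_per_save * dt - save_every) > 1e-9 * save_every) {
    stop("`dt` must divide `save_every` exactly", call. = FALSE)
  }
  n_saves <- floor(t_end / save_every + 1e-9)
  state <- initialize_state(params, grid, W_eq, noise_amplitude, seed)
  states <- vector("list", n_saves + 1L)
  states[[1L]] <- state
  clamp_W <- clamp_O <- clamped_mass <- 0
  for (i in seq_len(n_saves)) {
    state <- step_state(state, params, dt, n_per_save)
    clamp_W <- clamp_W + attr(state, "clamp_W_events")
    clamp_O <- clamp_O + attr(state, "clamp_O_events")
    clamped_mass <- clamped_mass + attr(state, "clamped_mass")
    states[[i + 1L]] <- state
  }
  config <- list(W_eq = W_eq, t_end = t_end, save_every = save_every,
                 dt = dt, noise_amplitude = noise_amplitude,
                 seed = as.integer(seed), rng_kind = "Mersenne-Twister")
  traj <- structure(
    list(states = states,
         times = vapply(states, function(s) s$t, numeric(1)),
         params = params, grid = grid, config = config,
         clamp_log = list(clamp_W_events = clamp_W,
                          clamp_O_events = clamp_O,
                          clamped_mass = clamped_mass)),
    class = "aeropattern_trajectory")
  if (!is.null(out_dir)) {
    write_trajectory(traj, out_dir)
  }
  traj
}

#' @export
print.aeropattern_trajectory <- function(x, ...) {
  cat(sprintf("<aeropattern_trajectory> %d snapshots to t = %.4g s (dt = %.4g s)\n",
              length(x$states), max(x$times), x$config$dt))
  cat(sprintf("  W_eq = %.4g worms/m^2 (%.3g /mm^2), seed = %d\n",
              x$config$W_eq, per_m2_to_per_mm2(x$config$W_eq), x$config$seed))
  if (x$clamp_log$clamp_W_events > 0 || x$clamp_log$clamp_O_events > 0) {
    cat(sprintf("  clamping: %g W events, %g O events\n",
                x$clamp_log$clamp_W_events, x$clamp_log$clamp_O_events))
  }
  invisible(x)
}
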