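#' Jacobian of the linearised worm/oxygen system at wavenumber k
#'
#' Linearising the coupled equations about the uniform equilibrium and
#' substituting a sinusoidal perturbation of wavenumber `k` gives a 2x2
#' system for the perturbation amplitudes (worm density, oxygen):
#' \deqn{J(k) = \begin{pmatrix} -D_W k^2 & -\beta W_{eq} k^2 \\
#'                              -k_c     & -D_O k^2 - f \end{pmatrix}}
#' with the transport coefficients \eqn{D_W}, \eqn{\beta} evaluated at the
#' equilibrium oxygen \eqn{O_{eq}} (the state the derivation linearises
#' around), not at ambient oxygen.
#'
#' @param params A [model_params()].
#' @param W_eq Uniform worm density, worms/m^2.
#' @param k Wavenumber, 1/m.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_at_k <- function(params, W_eq, k) {
  stopifnot(length(W_eq) == 1L, length(k) == 1L, k >= 0)
  eq <- equilibrium_oxygen(params, W_eq)
  D_W <- worm_diffusivity(params$curve, eq$O_eq)
  beta <- aerotaxis_coefficient(params$curve, eq$O_eq)
  matrix(c(-D_W * k^2,   -beta * W_eq * k^2,
           -params$k_c,  -params$D_O * k^2 - params$f),
         nrow = 2, byrow = TRUE)
}

#' Dispersion relation: perturbation growth rates versus wavenumber
#'
#' Closed-form eigenvalues of the linearised system,
#' \deqn{\lambda_\pm(k) = \tfrac12\left[-(D_W k^2 + D_O k^2 + f)
#'   \pm \sqrt{(D_W k^2 + D_O k^2 + f)^2
#'   - 4\,(D_W k^2 (D_O k^2 + f) - \beta W_{eq} k^2 k_c)}\right].}
#' A positive real part of \eqn{\lambda_+} at some `k` means the uniform
#' state is unstable to patterns of that wavenumber.
#'
#' @inheritParams jacobian_at_k
#' @param k Wavenumbers, 1/m (vectorised).
#' @return A tibble with columns `k`, `lambda_plus`, `lambda_minus`
#'   (complex, 1/s) and `growth` (Re \eqn{\lambda_+}, 1/s).
#' @examples
#' p <- model_params()
#' dr <- dispersion_relation(p, W_eq = 6e7, k = seq(100, 2.5e4, length.out = 200))
#' max(dr$growth)
#' @export
dispersion_relation <- function(params, W_eq, k) {
  stopifnot(length(W_eq) == 1L, all(k >= 0))
  eq <- equilibrium_oxygen(params, W_eq)
  D_W <- worm_diffusivity(params$curve, eq$O_eq)
  beta <- aerotaxis_coefficient(params$curve, eq$O_eq)
  P <- D_W * k^2
  Q <- params$D_O * k^2 + params$f
  det_term <- P * Q - beta * W_eq * k^2 * params$k_c
  disc <- as.complex((P + Q)^2 - 4 * det_term)
  root <- sqrt(disc)
  lp <- (-(P + Q) + root) / 2
  lm_ <- (-(P + Q) - root) / 2
  tibble::tibble(k = k, lambda_plus = lp, lambda_minus = lm_,
                 growth = Re(lp))
}

#' Linear instability criterion for the uniform state
#'
#' The uniform equilibrium is unstable iff
#' \eqn{W_{eq}\,\beta\,k_c > f\,D_W} with \eqn{\beta} and \eqn{D_W}
#' evaluated at \eqn{O_{eq}}; equivalently
#' \eqn{W_{eq}\,k_c\,V'(O_{eq}) > f\,V(O_{eq})}. Density and aerotactic
#' response favour instability, dispersal opposes it, which makes the
#' instability zone re-entrant in density: stable at low density, patterned
#' in between, stable again when crowding pushes \eqn{O_{eq}} down to the
#' velocity minimum where \eqn{\beta \to 0}.
#'
#' @inheritParams jacobian_at_k
#' @param W_eq Uniform worm densities, worms/m^2 (vectorised).
#' @return Logical vector.
#' @export
instability_criterion <- function(params, W_eq) {
  eq <- equilibrium_oxygen(params, W_eq)
  D_W <- worm_diffusivity(params$curve, eq$O_eq)
  beta <- aerotaxis_coefficient(params$curve, eq$O_eq)
  W_eq * beta * params$k_c > params$f * D_W
}

#' Upper edge of the unstable wavenumber band
#'
#' Solving \eqn{Re\,\lambda_+(k) > 0} for \eqn{k^2} gives the band
#' \eqn{0 < k^2 < (W_{eq}\beta k_c / D_W - f)/D_O}; the returned value is
#' that upper edge, clipped at zero when the uniform state is stable.
#'
#' @inheritParams instability_criterion
#' @return `k_sq_max` in 1/m^2 (vectorised over `W_eq`).
#' @export
unstable_band <- function(params, W_eq) {
  eq <- equilibrium_oxygen(params, W_eq)
  D_W <- worm_diffusivity(params$curve, eq$O_eq)
  beta <- aerotaxis_coefficient(params$curve, eq$O_eq)
  pmax(0, (W_eq * beta * params$k_c / D_W - params$f) / params$D_O)
}

#' Fastest-growing mode of the dispersion relation
#'
#' Scans Re \eqn{\lambda_+(k)} over the unstable band on a logarithmic grid
#' and refines the maximum by golden-section search. For a stable
#' configuration the growth maximum is non-positive and `k_star` is
#' reported as 0.
#'
#' @inheritParams jacobian_at_k
#' @param k_grid_resolution Number of scan points (default 512).
#' @return A one-row tibble: `unstable`, `k_sq_max` (1/m^2), `k_star` (1/m),
#'   `growth_max` (1/s).
#' @export
fastest_growing_mode <- function(params, W_eq, k_grid_resolution = 512) {
  stopifnot(length(W_eq) == 1L, k_grid_resolution >= 8)
  k_sq_max <- unstable_band(params, W_eq)
  if (k_sq_max <= 0) {
    # stable: scan a reference range just to report the (negative) supremum
    k_ref <- sqrt(params$f / params$D_O) * 10
    ks <- exp(seq(log(k_ref * 1e-4), log(k_ref), length.out = k_grid_resolution))
    g <- dispersion_relation(params, W_eq, ks)$growth
    return(tibble::tibble(unstable = FALSE, k_sq_max = 0, k_star = 0,
                          growth_max = min(max(g), 0)))
  }
  k_hi <- sqrt(k_sq_max)
  ks <- exp(seq(log(k_hi * 1e-4), log(k_hi), length.out = k_grid_resolution))
  g <- dispersion_relation(params, W_eq, ks)$growth
  # ties within 1e-12 resolved toward smaller k
  i <- which(g >= max(g) - 1e-12)[1]
  lo <- ks[max(1L, i - 1L)]
  hi <- ks[min(length(ks), i + 1L)]
  opt <- stats::optimize(function(k) dispersion_relation(params, W_eq, k)$growth,
                         interval = c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * k_hi)
  tibble::tibble(unstable = TRUE, k_sq_max = k_sq_max,
                 k_star = opt$maximum, growth_max = opt$objective)
}

# instability margin g(W) = W k_c V'(O_eq) - f V(O_eq); > 0 means unstable
instability_margin <- function(params, W) {
  O_eq <- params$O_am - params$k_c * W / params$f
  W * params$k_c * speed_slope(params$curve, O_eq) -
    params$f * worm_speed(params$curve, O_eq)
}

#' Critical densities bounding the instability zone
#'
#' Root-finds the instability margin
#' \eqn{g(W) = W k_c V'(O_{eq}(W)) - f V(O_{eq}(W))} over the feasible
#' density range by bisection. The zone is typically re-entrant: an
#' unstable interval \eqn{(W_{lower}, W_{upper})} bounded by stable uniform
#' densities on both sides.
#'
#' @param params A [model_params()].
#' @param O_am Ambient oxygen fraction; defaults to the value in `params`.
#' @param tol Relative bisection tolerance in W (default 1e-6).
#' @return A tibble with 0-2 rows: `root` ("W_lower"/"W_upper"), `W`
#'   (worms/m^2), `W_per_mm2`. Zero rows when the uniform state is stable
#'   at every feasible density.
#' @examples
#' critical_densities(model_params())
#' @export
critical_densities <- function(params, O_am = params$O_am, tol = 1e-6) {
  stopifnot(O_am > 0, O_am <= 1)
  params <- model_params(params$curve, params$D_O, params$f, params$k_c,
                         O_am, params$L)
  W_max <- max_feasible_density(params) * (1 - 1e-9)
  Ws <- seq(1, W_max, length.out = 4096)
  gs <- instability_margin(params, Ws)
  sgn <- sign(gs)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i) {
    stats::uniroot(function(W) instability_margin(params, W),
                   lower = Ws[i], upper = Ws[i + 1],
                   tol = tol * Ws[i + 1])$root
  }, numeric(1))
  roots <- sort(roots)
  if (length(roots) == 0) {
    return(tibble::tibble(root = character(), W = numeric(),
                          W_per_mm2 = numeric()))
  }
  labels <- if (length(roots) == 2) c("W_lower", "W_upper") else "W_lower"
  tibble::tibble(root = labels[seq_along(roots)], W = roots,
                 W_per_mm2 = per_m2_to_per_mm2(roots))
}

#' Stability phase diagram over density and ambient oxygen
#'
#' Evaluates the instability criterion (and, optionally, the fastest-growing
#' mode) on a density-by-ambient-oxygen grid. Cells whose equilibrium would
#' need negative oxygen (consumption exceeding supply) are labelled
#' infeasible rather than erroring.
#'
#' @param params A [model_params()] supplying the motility curve and rates.
#' @param W_grid Worm densities, worms/m^2.
#' @param O_am_grid Ambient oxygen fractions.
#' @param compute_modes If `TRUE` (default) also report `k_star` and
#'   `growth_max` for each feasible cell.
#' @return A tibble with one row per cell: `W`, `O_am`, `W_per_mm2`,
#'   `O_am_percent`, `feasible`, `unstable`, `k_star_per_m`,
#'   `growth_max_per_s`. Has class `aeropattern_phase_diagram` for
#'   [autoplot()].
#' @export
phase_diagram <- function(params, W_grid, O_am_grid, compute_modes = TRUE) {
  stopifnot(length(W_grid) >= 1, length(O_am_grid) >= 1)
  cells <- tidyr::expand_grid(W = sort(W_grid), O_am = sort(O_am_grid))
  res <- purrr::pmap_dfr(cells, function(W, O_am) {
    p <- model_params(params$curve, params$D_O, params$f, params$k_c,
                      O_am, params$L)
    if (W > max_feasible_density(p)) {
      return(tibble::tibble(feasible = FALSE, unstable = NA,
                            k_star_per_m = NA_real_,
                            growth_max_per_s = NA_real_))
    }
    if (!compute_modes) {
      return(tibble::tibble(feasible = TRUE,
                            unstable = instability_criterion(p, W),
                            k_star_per_m = NA_real_,
                            growth_max_per_s = NA_real_))
    }
    m <- fastest_growing_mode(p, W)
    tibble::tibble(feasible = TRUE, unstable = m$unstable,
                   k_star_per_m = m$k_star, growth_max_per_s = m$growth_max)
  })
  out <- dplyr::bind_cols(cells, res)
  out <- dplyr::mutate(out,
                       W_per_mm2 = per_m2_to_per_mm2(.data$W),
                       O_am_percent = 100 * .data$O_am,
                       .after = "O_am")
  class(out) <- c("aeropattern_phase_diagram", class(out))
  out
}
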