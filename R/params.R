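#' Full model parameter set
#'
#' Bundles the motility curve with the oxygen-field constants. All values are
#' canonical SI internally: metres, seconds, worm areal density in worms/m^2,
#' oxygen as a dimensionless fraction in \[0, 1\]. The defaults are the
#' calibrated values for aggregation on a standard bacterial lawn.
#'
#' `k_c` couples worm density to oxygen drawdown; its units are
#' oxygen-fraction m^2 / (worm s), so that `k_c * W` is an oxygen-fraction
#' rate when `W` is in worms/m^2.
#'
#' @param curve A [velocity_curve()].
#' @param D_O Surface oxygen diffusion coefficient, m^2/s.
#' @param f Oxygen penetration rate from air to the wet surface, 1/s.
#' @param k_c Oxygen consumption rate per unit worm density,
#'   oxygen-fraction m^2/(worm s).
#' @param O_am Ambient oxygen fraction in \[0, 1\].
#' @param L Side of the square periodic domain, m.
#'
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params()
#' equilibrium_oxygen(p, W_eq = 6e7)
#' @export
model_params <- function(curve = velocity_curve(),
                         D_O = 2e-9,
                         f = 0.65,
                         k_c = 7.3e-10,
                         O_am = 0.21,
                         L = 0.02) {
  stopifnot(inherits(curve, "velocity_curve"),
            is.numeric(D_O), is.numeric(f), is.numeric(k_c),
            is.numeric(O_am), is.numeric(L))
  if (D_O <= 0 || f <= 0 || k_c <= 0 || L <= 0) {
    stop("D_O, f, k_c and L must be strictly positive", call. = FALSE)
  }
  if (O_am < 0 || O_am > 1) {
    stop("O_am must be an oxygen fraction in [0, 1]", call. = FALSE)
  }
  structure(list(curve = curve, D_O = D_O, f = f, k_c = k_c,
                 O_am = O_am, L = L),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> (SI units)\n")
  cat(sprintf("  D_O = %.3g m^2/s, f = %.3g 1/s, k_c = %.3g O2-frac m^2/(worm s)\n",
              x$D_O, x$f, x$k_c))
  cat(sprintf("  O_am = %.3g, L = %.3g m\n", x$O_am, x$L))
  print(x$curve)
  invisible(x)
}

#' Uniform equilibrium of the coupled worm/oxygen system
#'
#' A spatially uniform worm density `W_eq` depresses the surface oxygen until
#' penetration balances consumption: \eqn{O_{eq} = O_{am} - k_c W_{eq}/f}.
#'
#' @param params A [model_params()].
#' @param W_eq Uniform worm areal density, worms/m^2 (vectorised).
#' @return A tibble with columns `W_eq`, `O_eq`.
#' @export
equilibrium_oxygen <- function(params, W_eq) {
  stopifnot(inherits(params, "model_params"), all(W_eq >= 0))
  O_eq <- params$O_am - params$k_c * W_eq / params$f
  # absorb rounding at the exact feasibility boundary
  O_eq[O_eq < 0 & O_eq > -1e-12 * max(params$O_am, 1)] <- 0
  if (any(O_eq < 0)) {
    stop("infeasible equilibrium: consumption exceeds supply (O_eq < 0) for W_eq >= ",
         format(max_feasible_density(params), digits = 6), " worms/m^2",
         call. = FALSE)
  }
  tibble::tibble(W_eq = W_eq, O_eq = O_eq)
}

#' Largest uniform density with a feasible (non-negative oxygen) equilibrium
#'
#' @param params A [model_params()].
#' @return Density f*O_am/k_c in worms/m^2.
#' @export
max_feasible_density <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$f * params$O_am / params$k_c
}

# unit helpers used at IO boundaries (internal canonical units are SI)
#' Convert worm density between worms/mm^2 and worms/m^2
#' @param x Density values.
#' @return Converted density.
#' @name density-units
NULL

#' @rdname density-units
#' @export
per_mm2_to_per_m2 <- function(x) x * 1e6

#' @rdname density-units
#' @export
per_m2_to_per_mm2 <- function(x) x / 1e6
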