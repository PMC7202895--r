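#' Oxygen-dependent motility curve
#'
#' Worms move at a speed set by the local oxygen fraction; a parabola
#' \eqn{V(O) = aO^2 + bO + c} captures the measured response: fast at very
#' low oxygen (dispersal), nearly stationary near the preferred level, and
#' fast again towards atmospheric oxygen where aerotaxis drives aggregation.
#' Together with the direction-change (tumbling) rate \eqn{\tau} the curve
#' determines both the worm diffusivity \eqn{D_W = V^2 / (2\tau)} and the
#' aerotactic coupling \eqn{\beta = (V/2\tau)\, dV/dO}.
#'
#' @param a Quadratic coefficient, m/s per squared oxygen fraction.
#' @param b Linear coefficient, m/s per oxygen fraction.
#' @param c Intercept speed at zero oxygen, m/s.
#' @param tau Direction-change rate, 1/s; must be positive.
#'
#' @return An object of class `velocity_curve`.
#' @examples
#' vc <- velocity_curve()
#' worm_speed(vc, c(0, 0.1, 0.21))
#' @export
velocity_curve <- function(a = 1.89e-2, b = -3.98e-3, c = 2.25e-4, tau = 0.5) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(tau),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(tau) == 1L,
            is.finite(a), is.finite(b), is.finite(c), is.finite(tau))
  if (tau <= 0) stop("`tau` must be a positive rate (1/s)", call. = FALSE)
  curve <- structure(list(a = a, b = b, c = c, tau = tau),
                     class = "velocity_curve")
  o <- seq(0, 0.21, length.out = 211)
  if (any(worm_speed(curve, o) <= 0)) {
    stop("V(O) must be positive over the operating range [0, 0.21]",
         call. = FALSE)
  }
  curve
}

#' @export
print.velocity_curve <- function(x, ...) {
  cat("<velocity_curve>  V(O) = a O^2 + b O + c\n")
  cat(sprintf("  a = %.4g m/s, b = %.4g m/s, c = %.4g m/s, tau = %.3g 1/s\n",
              x$a, x$b, x$c, x$tau))
  o_min <- -x$b / (2 * x$a)
  cat(sprintf("  vertex at O = %.4f (V = %.4g m/s)\n",
              o_min, worm_speed(x, o_min)))
  invisible(x)
}

#' Worm crawling speed at a given oxygen fraction
#'
#' @param curve A [velocity_curve()].
#' @param O Oxygen fraction(s), dimensionless (0.21 = atmospheric).
#' @return Speed in m/s, vectorised over `O`.
#' @export
worm_speed <- function(curve, O) {
  stopifnot(inherits(curve, "velocity_curve"), all(O >= 0))
  curve$a * O^2 + curve$b * O + curve$c
}

#' Slope of the motility curve dV/dO
#'
#' @inheritParams worm_speed
#' @return dV/dO in m/s per oxygen fraction.
#' @export
speed_slope <- function(curve, O) {
  stopifnot(inherits(curve, "velocity_curve"), all(O >= 0))
  2 * curve$a * O + curve$b
}

#' Motility-derived worm diffusivity
#'
#' In two dimensions a run-and-tumble walker at speed \eqn{V} reorienting at
#' rate \eqn{\tau} disperses diffusively with \eqn{D_W = V^2/(2\tau)}.
#'
#' @inheritParams worm_speed
#' @return Diffusivity in m^2/s, vectorised over `O`.
#' @export
worm_diffusivity <- function(curve, O) {
  worm_speed(curve, O)^2 / (2 * curve$tau)
}

#' Aerotactic coupling coefficient
#'
#' \eqn{\beta(O) = (V/2\tau)\, dV/dO} measures how strongly worms drift along
#' oxygen gradients; its sign follows the slope of the motility curve, so
#' worms climb gradients above the velocity minimum (aggregation-promoting
#' regime) and descend them below it.
#'
#' @inheritParams worm_speed
#' @return Coupling in m^2/s per oxygen fraction, vectorised over `O`.
#' @export
aerotaxis_coefficient <- function(curve, O) {
  worm_speed(curve, O) / (2 * curve$tau) * speed_slope(curve, O)
}
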