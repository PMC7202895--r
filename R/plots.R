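#' Plot a worm-density field
#'
#' @param state A `field_state` (or a plain matrix together with `grid`).
#' @param grid A [grid2d()]; taken from `state` when omitted.
#' @param which `"W"` (default) or `"O"`.
#' @return A ggplot raster of the field in millimetre coordinates.
#' @export
plot_field <- function(state, grid = NULL, which = c("W", "O")) {
  which <- match.arg(which)
  if (inherits(state, "field_state")) {
    grid <- state$grid
    field <- state[[which]]
    t_lab <- sprintf("t = %.4g s", state$t)
  } else {
    stopifnot(is.matrix(state), inherits(grid, "grid2d"))
    field <- state
    t_lab <- NULL
  }
  N <- nrow(field)
  df <- tibble::tibble(
    x = rep((seq_len(N) - 0.5) * grid$dx * 1e3, ncol(field)),
    y = rep((seq_len(ncol(field)) - 0.5) * grid$dx * 1e3, each = N),
    value = as.vector(field))
  lab <- if (which == "W") "worms/m²" else "O₂ fraction"
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = t_lab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.field_state <- function(object, ...) plot_field(object, ...)

#' @export
autoplot.aeropattern_phase_diagram <- function(object, ...) {
  df <- dplyr::mutate(object, state = dplyr::case_when(
    !.data$feasible ~ "infeasible",
    .data$unstable ~ "unstable (patterns)",
    TRUE ~ "stable (uniform)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$W_per_mm2, .data$O_am_percent,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      "stable (uniform)" = "grey85", "unstable (patterns)" = "#d95f02",
      "infeasible" = "grey40"), name = NULL) +
    ggplot2::labs(x = "worm density (worms/mm²)",
                  y = "ambient oxygen (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aeropattern_coarsening <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$length_m)),
                  ggplot2::aes(.data$t / 60, .data$length_m * 1e3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
    ggplot2::labs(x = "time (min)", y = "characteristic length (mm)",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.structure_spectrum <- function(object, ...) {
  if (object$no_peak) stop("constant field: nothing to plot", call. = FALSE)
  ggplot2::ggplot(object$spectrum, ggplot2::aes(.data$k, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k_peak, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wavenumber k (1/m)", y = "radially averaged power") +
    ggplot2::theme_minimal()
}

#' Plot the dispersion relation for one or more densities
#'
#' @param params A [model_params()].
#' @param W_eq Worm densities, worms/m^2.
#' @param k_max Upper wavenumber, 1/m; default 1.2x the widest band edge
#'   (or a penetration-based scale when all configurations are stable).
#' @return A ggplot of Re \eqn{\lambda_+}(k) per density.
#' @export
plot_dispersion <- function(params, W_eq, k_max = NULL) {
  if (is.null(k_max)) {
    bands <- vapply(W_eq, function(w) unstable_band(params, w), numeric(1))
    k_max <- if (max(bands) > 0) 1.2 * sqrt(max(bands)) else
      sqrt(params$f / params$D_O)
  }
  ks <- seq(k_max / 400, k_max, length.out = 400)
  df <- purrr::map_dfr(W_eq, function(w) {
    dplyr::mutate(dispersion_relation(params, w, ks),
                  W_per_mm2 = per_m2_to_per_mm2(w))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$growth,
                                   colour = factor(.data$W_per_mm2))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber k (1/m)",
                  y = expression(Re ~ lambda["+"] ~ (s^-1)),
                  colour = "worms/mm²") +
    ggplot2::theme_minimal()
}
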