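# Connected components of a logical mask under periodic (wrap-around)
# 4-connectivity; returns per-component cell counts and perimeters
# (perimeter = number of cell edges facing the other phase, in cell units).
periodic_components <- function(mask) {
  N <- nrow(mask)
  M <- ncol(mask)
  idx <- matrix(seq_len(N * M), N, M)
  east <- idx[c(2:N, 1), , drop = FALSE]
  north <- idx[, c(2:M, 1), drop = FALSE]
  keep_e <- mask & mask[c(2:N, 1), , drop = FALSE]
  keep_n <- mask & mask[, c(2:M, 1), drop = FALSE]
  edges <- rbind(cbind(idx[keep_e], east[keep_e]),
                 cbind(idx[keep_n], north[keep_n]))
  nodes <- which(mask)
  if (length(nodes) == 0) {
    return(list(n = 0L, sizes = integer(), perimeters = integer()))
  }
  rank <- integer(N * M)
  rank[nodes] <- seq_along(nodes)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(cbind(rank[edges[, 1]], rank[edges[, 2]])))
  }
  comp <- igraph::components(g)
  # perimeter: per-cell count of 4-neighbours in the other phase
  other_e <- mask & !mask[c(2:N, 1), , drop = FALSE]
  other_w <- mask & !mask[c(N, 1:(N - 1)), , drop = FALSE]
  other_n <- mask & !mask[, c(2:M, 1), drop = FALSE]
  other_s <- mask & !mask[, c(M, 1:(M - 1)), drop = FALSE]
  exposed <- (other_e + other_w + other_n + other_s)[nodes]
  perims <- vapply(seq_len(comp$no), function(i) {
    sum(exposed[comp$membership == i])
  }, numeric(1))
  list(n = comp$no, sizes = as.integer(comp$csize), perimeters = perims)
}

#' Classify the morphology of a density field
#'
#' Deterministic closure of the visual dots/stripes/holes taxonomy:
#' a field with coefficient of variation below `cv_threshold` is `uniform`;
#' otherwise it is binarised at its mean and the high-phase area fraction
#' `phi` and the periodic 4-connected components of both phases decide the
#' label. A component is "compact" when its perimeter^2/area (cell units)
#' is below `compactness_max` (a digitised disc scores about 20, an
#' elongated band far more). `phi < phi_low` with at least `min_components`
#' compact high-phase blobs is `dots`; `phi > phi_high` with as many
#' compact low-phase blobs is `holes`; anything else is `stripes`.
#'
#' @param field Numeric matrix of worm density (finite, non-negative).
#' @param cv_threshold Uniformity threshold on the coefficient of variation
#'   (default 0.05).
#' @param phi_low,phi_high Area-fraction bounds for dots/holes (default
#'   0.4 / 0.6).
#' @param compactness_max Perimeter^2/area bound for a compact component
#'   (default 30).
#' @param min_components Minimum number of compact components (default 3).
#' @return One of `"uniform"`, `"dots"`, `"stripes"`, `"holes"`.
#' @examples
#' g <- grid2d(N = 64, L = 0.02)
#' classify_pattern(make_pattern_fixture("dots", g, wavelength = 0.004, seed = 1))
#' @export
classify_pattern <- function(field, cv_threshold = 0.05,
                             phi_low = 0.4, phi_high = 0.6,
                             compactness_max = 30, min_components = 3) {
  pattern_summary(field, cv_threshold, phi_low, phi_high,
                  compactness_max, min_components)$label
}

#' Morphology metrics of a density field
#'
#' The quantities behind [classify_pattern()], returned as a one-row tibble
#' for tabular export.
#'
#' @inheritParams classify_pattern
#' @return A tibble: `label`, `cv`, `phi`, `n_components_high`,
#'   `n_components_low`, `n_compact_high`, `n_compact_low`.
#' @export
pattern_summary <- function(field, cv_threshold = 0.05,
                            phi_low = 0.4, phi_high = 0.6,
                            compactness_max = 30, min_components = 3) {
  if (!is.matrix(field) || !all(is.finite(field))) {
    stop("`field` must be a finite numeric matrix", call. = FALSE)
  }
  if (any(field < 0)) stop("`field` must be non-negative", call. = FALSE)
  m <- mean(field)
  cv <- if (m > 0) stats::sd(field) / m else 0
  if (cv < cv_threshold) {
    return(tibble::tibble(label = "uniform", cv = cv, phi = NA_real_,
                          n_components_high = NA_integer_,
                          n_components_low = NA_integer_,
                          n_compact_high = NA_integer_,
                          n_compact_low = NA_integer_))
  }
  high <- field > m
  phi <- mean(high)
  ch <- periodic_components(high)
  cl <- periodic_components(!high)
  n_compact_high <- sum(ch$perimeters^2 / ch$sizes < compactness_max)
  n_compact_low <- sum(cl$perimeters^2 / cl$sizes < compactness_max)
  label <- if (phi < phi_low && n_compact_high >= min_components) {
    "dots"
  } else if (phi > phi_high && n_compact_low >= min_components) {
    "holes"
  } else {
    "stripes"
  }
  tibble::tibble(label = label, cv = cv, phi = phi,
                 n_components_high = ch$n, n_components_low = cl$n,
                 n_compact_high = as.integer(n_compact_high),
                 n_compact_low = as.integer(n_compact_low))
}

#' Radially averaged structure spectrum of a field
#'
#' Mean-subtracts the field, takes the 2-D power spectrum and averages it
#' in radial wavenumber bins of width `2 pi / L` (the domain fundamental),
#' excluding the zero mode. The spectral peak gives the characteristic
#' pattern length `2 pi / k_peak`; the peak is flagged unreliable when its
#' power is less than twice the median bin power (as for white noise).
#'
#' @param field Numeric matrix.
#' @param grid A [grid2d()] giving physical dimensions.
#' @return An object of class `structure_spectrum`: list with `spectrum`
#'   (tibble `k`, `power`, `n_modes`), `k_peak` (1/m),
#'   `characteristic_length` (m), `peak_reliable`, `no_peak`.
#' @export
structure_spectrum <- function(field, grid) {
  stopifnot(is.matrix(field), inherits(grid, "grid2d"),
            nrow(field) == grid$N, ncol(field) == grid$N)
  if (!all(is.finite(field))) stop("`field` must be finite", call. = FALSE)
  N <- grid$N
  f0 <- field - mean(field)
  if (sum(f0^2) < 1e-24 * max(1, mean(field))^2 * N^2) {
    return(structure(list(spectrum = tibble::tibble(k = numeric(),
                                                    power = numeric()),
                          k_peak = NA_real_,
                          characteristic_length = NA_real_,
                          peak_reliable = FALSE, no_peak = TRUE),
                     class = "structure_spectrum"))
  }
  P <- Mod(stats::fft(f0))^2 / N^4
  dk <- 2 * pi / grid$L
  m <- c(0:(N %/% 2), -((N - (N %/% 2 + 1)):1))
  kmag <- sqrt(outer(m^2, m^2, "+")) * dk
  bin <- round(kmag / dk)
  keep <- bin > 0
  pw <- tapply(P[keep], bin[keep], mean)
  nmodes <- tapply(P[keep], bin[keep], length)
  ks <- as.numeric(names(pw)) * dk
  ord <- order(ks)
  spec <- tibble::tibble(k = ks[ord], power = as.numeric(pw)[ord],
                         n_modes = as.integer(nmodes)[ord])
  i_pk <- which.max(spec$power)
  # peak reliability: prominent over the median bin power AND statistically
  # incompatible with a flat spectrum. Each bin averages n_modes periodogram
  # ordinates, so under a flat (white-noise) spectrum its relative sampling
  # fluctuation is ~ 1/sqrt(n_modes); a z-score on the peak bin separates
  # real spectral peaks from the maxima of flat-spectrum noise, which land
  # in sparse low-k bins and rarely exceed z ~ 4.
  med <- stats::median(spec$power)
  ratio <- spec$power[i_pk] / med
  z <- (ratio - 1) * sqrt(spec$n_modes[i_pk])
  reliable <- ratio >= 2 && z >= 5
  # sub-bin peak localisation: quadratic interpolation of log power through
  # the peak bin and its neighbours (avoids quantising the characteristic
  # length to the radial bin width)
  k_peak <- spec$k[i_pk]
  if (i_pk > 1 && i_pk < nrow(spec) &&
      abs(spec$k[i_pk + 1] - 2 * spec$k[i_pk] + spec$k[i_pk - 1]) < 1e-9 * dk) {
    lp <- log(spec$power[(i_pk - 1):(i_pk + 1)] + .Machine$double.xmin)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (denom < 0) {
      shift <- 0.5 * (lp[1] - lp[3]) / denom
      k_peak <- spec$k[i_pk] + max(-0.5, min(0.5, shift)) *
        (spec$k[i_pk + 1] - spec$k[i_pk])
    }
  }
  structure(list(spectrum = spec, k_peak = k_peak,
                 characteristic_length = 2 * pi / k_peak,
                 peak_reliable = reliable, no_peak = FALSE),
            class = "structure_spectrum")
}

#' @export
print.structure_spectrum <- function(x, ...) {
  if (x$no_peak) {
    cat("<structure_spectrum> constant field: no peak\n")
  } else {
    cat(sprintf("<structure_spectrum> k_peak = %.4g 1/m, length = %.4g m (%s)\n",
                x$k_peak, x$characteristic_length,
                if (x$peak_reliable) "reliable" else "unreliable peak"))
  }
  invisible(x)
}

#' Coarsening curve of a simulated trajectory
#'
#' Characteristic pattern length per saved frame. Once patterns emerge from
#' the instability they merge and the dominant length scale grows; the
#' returned tibble records that growth and the attached attribute
#' `coarsening` states whether the series is non-decreasing (within
#' `tolerance`) from the first patterned frame to the last.
#'
#' @param trajectory An `aeropattern_trajectory` (from [run_simulation()])
#'   with at least 3 saved frames.
#' @param tolerance Relative tolerance for the non-decreasing check
#'   (default 0.05).
#' @return A tibble with columns `t`, `label`, `length_m`, `peak_reliable`;
#'   attributes `coarsening` (logical) and `first_patterned` (index or NA).
#'   Class `aeropattern_coarsening` for [autoplot()].
#' @export
coarsening_curve <- function(trajectory, tolerance = 0.05) {
  stopifnot(inherits(trajectory, "aeropattern_trajectory"))
  if (length(trajectory$states) < 3) {
    stop("coarsening needs at least 3 saved frames", call. = FALSE)
  }
  rows <- purrr::map_dfr(trajectory$states, function(s) {
    sp <- structure_spectrum(s$W, s$grid)
    tibble::tibble(t = s$t,
                   label = classify_pattern(s$W),
                   length_m = if (sp$no_peak) NA_real_ else sp$characteristic_length,
                   peak_reliable = !sp$no_peak && sp$peak_reliable)
  })
  patterned <- which(rows$label != "uniform" & rows$peak_reliable)
  if (length(patterned) >= 2) {
    i0 <- patterned[1]
    i1 <- patterned[length(patterned)]
    coars <- rows$length_m[i1] >= rows$length_m[i0] * (1 - tolerance)
    attr(rows, "first_patterned") <- i0
  } else {
    coars <- NA
    attr(rows, "first_patterned") <- NA_integer_
  }
  attr(rows, "coarsening") <- coars
  class(rows) <- c("aeropattern_coarsening", class(rows))
  rows
}

#' Decay length of a bacterial gradient across a swarm
#'
#' Food diffusing into a consuming swarm from its leading edge decays over
#' \eqn{\lambda = \sqrt{D_b / f_b}}; this length sets the width of the
#' motile swarm body.
#'
#' @param D_b Bacterial diffusion coefficient, m^2/s.
#' @param f_b Bacterial consumption rate, 1/s.
#' @return Decay length in metres (vectorised).
#' @examples
#' gradient_decay_length(4e-10, 1e-4)  # 2 mm
#' @export
gradient_decay_length <- function(D_b, f_b) {
  if (any(D_b <= 0) || any(f_b <= 0)) {
    stop("`D_b` and `f_b` must be positive", call. = FALSE)
  }
  sqrt(D_b / f_b)
}
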