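new_fit_result <- function(estimates, std_errors = NULL, sigma = NA_real_,
                           nobs = NA_integer_, converged = TRUE,
                           method = NA_character_, flags = character()) {
  structure(list(estimates = estimates, std_errors = std_errors,
                 sigma = sigma, nobs = nobs, converged = converged,
                 method = method, flags = flags),
            class = "aeropattern_fit")
}

#' @export
print.aeropattern_fit <- function(x, ...) {
  cat(sprintf("<aeropattern_fit> %s%s\n", x$method,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (nm in names(x$estimates)) {
    se <- if (!is.null(x$std_errors) && nm %in% names(x$std_errors)) {
      sprintf(" (se %.3g)", x$std_errors[[nm]])
    } else ""
    cat(sprintf("  %s = %.6g%s\n", nm, x$estimates[[nm]], se))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_velocity_curve Coefficient-level summary (broom-style).
#' @param x An `aeropattern_fit`.
#' @param ... Unused.
#' @export
tidy.aeropattern_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unlist(x$estimates, use.names = FALSE),
                 std.error = if (is.null(x$std_errors)) {
                   NA_real_
                 } else {
                   unlist(x$std_errors, use.names = FALSE)[
                     match(names(x$estimates), names(x$std_errors))]
                 })
}

#' @describeIn fit_velocity_curve One-row fit summary (broom-style).
#' @export
glance.aeropattern_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, sigma = x$sigma, nobs = x$nobs,
                 method = x$method,
                 flags = paste(x$flags, collapse = ";"))
}

#' Fit the parabolic motility curve to speed-versus-oxygen data
#'
#' Ordinary least-squares quadratic fit of measured crawling speeds against
#' oxygen fraction, recovering the coefficients of
#' \eqn{V(O) = aO^2 + bO + c}.
#'
#' @param data A data frame with columns `O` (oxygen fraction) and `V`
#'   (speed, m/s), e.g. from [sample_velocity_measurements()].
#' @return An `aeropattern_fit` with estimates `a`, `b`, `c` and their
#'   standard errors; use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' d <- sample_velocity_measurements(velocity_curve(), seq(0, 0.21, 0.03))
#' tidy(fit_velocity_curve(d))
#' @export
fit_velocity_curve <- function(data) {
  stopifnot(is.data.frame(data), all(c("O", "V") %in% names(data)))
  if (length(unique(data$O)) < 3) {
    stop("need >= 3 distinct oxygen levels to fit a parabola", call. = FALSE)
  }
  fit <- stats::lm(V ~ I(O^2) + O, data = data)
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(suppressWarnings(stats::vcov(fit)))), error = function(e) rep(NA_real_, 3))
  new_fit_result(
    estimates = list(a = unname(est["I(O^2)"]), b = unname(est["O"]),
                     c = unname(est["(Intercept)"])),
    std_errors = list(a = unname(se["I(O^2)"]), b = unname(se["O"]),
                      c = unname(se["(Intercept)"])),
    sigma = suppressWarnings(summary(fit)$sigma), nobs = nrow(data),
    method = "OLS quadratic V(O)")
}

#' Estimate the oxygen penetration rate from a worm-free relaxation trace
#'
#' With no consumers, surface oxygen relaxes to ambient as
#' \eqn{O(t) = O_{am} - (O_{am} - O_0) e^{-f t}}; a log-linear regression
#' of \eqn{\log(O_{am} - O)} on time recovers `f` as minus the slope.
#'
#' Once the deficit has decayed into the measurement noise, its logarithm is
#' noise rather than signal and would badly bias the slope; the estimator
#' therefore gauges the noise floor from the final 10% of the trace (where
#' the exponential is most decayed) and fits only the initial contiguous
#' segment before the observed deficit first drops below five times that
#' floor. The fitted segment must stay strictly below `O_am`.
#'
#' @param data Data frame with columns `t` (s) and `O` (oxygen fraction).
#' @param O_am Ambient oxygen fraction.
#' @return An `aeropattern_fit` with estimate `f` (1/s). A non-positive
#'   slope is flagged `non_identifiable` and `converged` is `FALSE`.
#' @export
estimate_penetration_rate <- function(data, O_am) {
  stopifnot(is.data.frame(data), all(c("t", "O") %in% names(data)))
  data <- data[order(data$t), ]
  deficit <- O_am - data$O
  late <- data$t >= stats::quantile(data$t, 0.9)
  noise_floor <- if (sum(late) >= 5) stats::sd(data$O[late]) else 0
  below <- which(deficit < 5 * noise_floor)
  keep <- if (length(below)) seq_len(below[1] - 1L) else seq_along(deficit)
  if (length(keep) < 3) {
    stop("fewer than 3 trace points above the noise floor", call. = FALSE)
  }
  if (any(deficit[keep] <= 0)) {
    stop("trace touches or exceeds O_am: log(O_am - O) undefined", call. = FALSE)
  }
  fit <- stats::lm(log(deficit[keep]) ~ t,
                   data = data.frame(t = data$t[keep]))
  f_hat <- -unname(stats::coef(fit)["t"])
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))["t"]
  flags <- character()
  converged <- TRUE
  if (f_hat <= 1e-12) {
    flags <- "non_identifiable"
    converged <- FALSE
  }
  new_fit_result(list(f = f_hat), list(f = unname(se)),
                 sigma = suppressWarnings(summary(fit)$sigma),
                 nobs = length(keep),
                 converged = converged,
                 method = "log-linear relaxation", flags = flags)
}

#' Estimate the consumption coefficient from equilibrium density/oxygen pairs
#'
#' At uniform equilibrium, consumption balances penetration:
#' \eqn{k_c W = f (O_{am} - O_{eq})}. Regressing \eqn{f (O_{am} - O_{eq})}
#' on `W` through the origin recovers `k_c`.
#'
#' @param data Data frame with columns `W` (worms/m^2) and `O_eq`
#'   (oxygen fraction), e.g. from [make_equilibrium_dataset()].
#' @param f Penetration rate, 1/s.
#' @param O_am Ambient oxygen fraction.
#' @return An `aeropattern_fit` with estimate `k_c`.
#' @export
estimate_consumption_rate <- function(data, f, O_am) {
  stopifnot(is.data.frame(data), all(c("W", "O_eq") %in% names(data)))
  if (length(unique(data$W)) < 2) {
    stop("need >= 2 distinct densities", call. = FALSE)
  }
  y <- f * (O_am - data$O_eq)
  fit <- stats::lm(y ~ W + 0, data = data.frame(W = data$W))
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))["W"]
  new_fit_result(list(k_c = unname(stats::coef(fit)["W"])),
                 list(k_c = unname(se)),
                 sigma = suppressWarnings(summary(fit)$sigma), nobs = nrow(data),
                 method = "through-origin equilibrium balance")
}

# ensemble mean-squared displacement from a tidy trajectory table
ensemble_msd <- function(data) {
  t0 <- min(data$t)
  start <- dplyr::filter(data, .data$t == t0)
  d <- dplyr::left_join(data, dplyr::select(start, "walker", x0 = "x", y0 = "y"),
                        by = "walker")
  d <- dplyr::mutate(d, sq = (.data$x - .data$x0)^2 + (.data$y - .data$y0)^2)
  dplyr::summarise(dplyr::group_by(d, .data$t), msd = mean(.data$sq),
                   .groups = "drop")
}

#' Estimate the direction-change rate from run-and-tumble trajectories
#'
#' A constant-speed run-and-tumble walker in 2-D is diffusive at long
#' times with \eqn{MSD = 4 D t} and \eqn{D = V^2/(2\tau)}. The ensemble
#' MSD slope over a long-time window gives \eqn{\hat D}, inverted to
#' \eqn{\hat\tau = V^2 / (2 \hat D)}. By default the window is chosen in
#' two passes: a first fit on `[T/10, T/2]` gives a provisional
#' \eqn{\hat\tau_0}, then the final fit uses `[5/tau_hat0, T/2]` so the
#' ballistic transient (duration ~ `1/tau`) is excluded.
#'
#' @param data Tidy trajectory table with columns `walker`, `t`, `x`, `y`
#'   (e.g. from [simulate_run_and_tumble()]).
#' @param V Walker speed, m/s.
#' @param window Optional explicit fit window `c(t_min, t_max)` in seconds.
#' @return An `aeropattern_fit` with estimates `tau` (1/s) and `D`
#'   (m^2/s). Flags: `short_trajectory` when the duration is below
#'   `10/tau_hat`; `superdiffusive` when the MSD grows markedly faster
#'   than linearly in the window (e.g. a ballistic, turn-free trajectory).
#' @export
estimate_turn_rate <- function(data, V, window = NULL) {
  stopifnot(is.data.frame(data),
            all(c("walker", "t", "x", "y") %in% names(data)), V > 0)
  msd <- ensemble_msd(data)
  T_end <- max(msd$t)
  fit_D <- function(win) {
    m <- dplyr::filter(msd, .data$t >= win[1], .data$t <= win[2], .data$t > 0)
    if (nrow(m) < 3) stop("fewer than 3 MSD points in the fit window", call. = FALSE)
    fit <- stats::lm(msd ~ t, data = m)
    list(D = unname(stats::coef(fit)["t"]) / 4,
         se = sqrt(diag(suppressWarnings(stats::vcov(fit))))["t"] / 4,
         expo = unname(stats::coef(stats::lm(log(msd) ~ log(t), data = m))[2]))
  }
  if (is.null(window)) {
    first <- fit_D(c(T_end / 10, T_end / 2))
    tau0 <- V^2 / (2 * max(first$D, .Machine$double.eps))
    window <- c(min(5 / tau0, T_end / 4), T_end / 2)
  }
  res <- fit_D(window)
  tau_hat <- V^2 / (2 * res$D)
  flags <- character()
  if (T_end < 10 / tau_hat) flags <- c(flags, "short_trajectory")
  if (res$expo > 1.5) flags <- c(flags, "superdiffusive")
  new_fit_result(list(tau = tau_hat, D = res$D),
                 list(tau = tau_hat * unname(res$se) / res$D,
                      D = unname(res$se)),
                 nobs = length(unique(data$walker)),
                 converged = length(flags) == 0,
                 method = sprintf("ensemble MSD slope, window [%.3g, %.3g] s",
                                  window[1], window[2]),
                 flags = flags)
}

#' Estimate the surface oxygen diffusion coefficient from a spreading bump
#'
#' Under pure diffusion a compact bump's per-axis spatial variance grows as
#' \eqn{\sigma^2(t) = \sigma^2(0) + 2 D t}; fitting that line on each axis
#' and averaging recovers `D`. Fields are normalised to unit mass before
#' the variance is taken.
#'
#' @param trajectory An `aeropattern_trajectory` whose oxygen fields evolve
#'   under diffusion only (no penetration, no worms), e.g. from
#'   [simulate_diffusion_bump()].
#' @return An `aeropattern_fit` with estimate `D_O` (m^2/s) and the
#'   per-axis estimates `D_x`, `D_y`.
#' @export
estimate_oxygen_diffusion <- function(trajectory) {
  stopifnot(inherits(trajectory, "aeropattern_trajectory"))
  grid <- trajectory$grid
  xc <- (seq_len(grid$N) - 0.5) * grid$dx
  axis_var <- function(field) {
    p <- field / sum(field)
    px <- rowSums(p)
    py <- colSums(p)
    c(sum(px * xc^2) - sum(px * xc)^2,
      sum(py * xc^2) - sum(py * xc)^2)
  }
  v0 <- axis_var(trajectory$states[[1]]$O)
  if (any(sqrt(v0) > grid$L / 8)) {
    stop("initial bump too wide (sigma > L/8): periodic wrap would bias the variance",
         call. = FALSE)
  }
  vs <- t(vapply(trajectory$states, function(s) axis_var(s$O), numeric(2)))
  ts <- trajectory$times
  slope_x <- unname(stats::coef(stats::lm(vs[, 1] ~ ts))[2])
  slope_y <- unname(stats::coef(stats::lm(vs[, 2] ~ ts))[2])
  new_fit_result(list(D_O = (slope_x + slope_y) / 4,
                      D_x = slope_x / 2, D_y = slope_y / 2),
                 nobs = length(ts),
                 method = "per-axis variance growth sigma^2 = sigma0^2 + 2Dt")
}
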