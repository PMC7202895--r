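# recognised config keys: value -> SI converter
config_converters <- list(
  a_m_per_s = list(field = "a", to_si = identity),
  b_m_per_s = list(field = "b", to_si = identity),
  c_m_per_s = list(field = "c", to_si = identity),
  tau_per_s = list(field = "tau", to_si = identity),
  D_O_m2_per_s = list(field = "D_O", to_si = identity),
  D_O_cm2_per_s = list(field = "D_O", to_si = function(x) x * 1e-4),
  f_per_s = list(field = "f", to_si = identity),
  k_c_o2_m2_per_worm_s = list(field = "k_c", to_si = identity),
  O_am_fraction = list(field = "O_am", to_si = identity),
  O_am_percent = list(field = "O_am", to_si = function(x) x / 100),
  L_m = list(field = "L", to_si = identity),
  L_cm = list(field = "L", to_si = function(x) x * 1e-2),
  N = list(field = "N", to_si = identity),
  W_eq_per_m2 = list(field = "W_eq", to_si = identity),
  W_eq_per_mm2 = list(field = "W_eq", to_si = function(x) x * 1e6),
  dt_s = list(field = "dt", to_si = identity),
  t_end_s = list(field = "t_end", to_si = identity),
  save_every_s = list(field = "save_every", to_si = identity),
  noise_amplitude = list(field = "noise_amplitude", to_si = identity),
  seed = list(field = "seed", to_si = identity)
)

#' Load a model/simulation configuration file
#'
#' Reads a flat YAML (or JSON) key/value file whose keys carry explicit
#' unit suffixes (e.g. `D_O_cm2_per_s`, `W_eq_per_mm2`, `O_am_percent`)
#' and converts everything to canonical SI on load. Missing keys fall back
#' to the package defaults; unknown keys are errors, as are conflicting
#' unit variants of the same quantity and non-positive physical constants.
#'
#' @param path Path to a YAML/JSON file. `NULL` returns pure defaults.
#' @return A list: `params` ([model_params()]), `grid` ([grid2d()]), `sim`
#'   (list `W_eq`, `dt`, `t_end`, `save_every`, `noise_amplitude`, `seed`).
#' @examples
#' cfg <- load_config(NULL)  # package defaults
#' cfg$params$f
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (length(raw) && (is.null(names(raw)) || any(names(raw) == ""))) {
    stop("config must be a flat mapping of named keys", call. = FALSE)
  }
  unknown <- setdiff(names(raw), names(config_converters))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; recognised keys: ", paste(names(config_converters), collapse = ", "),
         call. = FALSE)
  }
  vals <- list()
  for (key in names(raw)) {
    cv <- config_converters[[key]]
    v <- raw[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config key `", key, "` must be a single finite number",
           call. = FALSE)
    }
    if (!is.null(vals[[cv$field]])) {
      stop("conflicting unit variants given for `", cv$field, "`",
           call. = FALSE)
    }
    vals[[cv$field]] <- cv$to_si(v)
  }
  defaults <- list(a = 1.89e-2, b = -3.98e-3, c = 2.25e-4, tau = 0.5,
                   D_O = 2e-9, f = 0.65, k_c = 7.3e-10, O_am = 0.21,
                   L = 0.02, N = 256, W_eq = 6e7, dt = NA_real_,
                   t_end = 600, save_every = 60, noise_amplitude = 0.01,
                   seed = 1)
  vals <- utils::modifyList(defaults, vals)
  for (nm in c("tau", "D_O", "f", "k_c", "L")) {
    if (vals[[nm]] <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  params <- model_params(velocity_curve(vals$a, vals$b, vals$c, vals$tau),
                         D_O = vals$D_O, f = vals$f, k_c = vals$k_c,
                         O_am = vals$O_am, L = vals$L)
  list(params = params,
       grid = grid2d(vals$N, vals$L),
       sim = list(W_eq = vals$W_eq, dt = vals$dt, t_end = vals$t_end,
                  save_every = vals$save_every,
                  noise_amplitude = vals$noise_amplitude,
                  seed = as.integer(vals$seed)))
}

params_as_list <- function(params) {
  list(a_m_per_s = params$curve$a, b_m_per_s = params$curve$b,
       c_m_per_s = params$curve$c, tau_per_s = params$curve$tau,
       D_O_m2_per_s = params$D_O, f_per_s = params$f,
       k_c_o2_m2_per_worm_s = params$k_c, O_am_fraction = params$O_am,
       L_m = params$L)
}

content_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a field snapshot with a JSON metadata sidecar
#'
#' The arrays go into an R-native binary container (`.rds`); grid, time,
#' units and array shape go into a human-readable `<path>.json` sidecar.
#' The round-trip through [read_snapshot()] is bit-exact.
#'
#' @param state A `field_state`.
#' @param path Output path (conventionally ending in `.rds`).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "field_state"))
  saveRDS(list(W = state$W, O = state$O), path)
  meta <- list(t_s = state$t, N = state$grid$N, L_m = state$grid$L,
               dx_m = state$grid$dx, shape = dim(state$W),
               units = list(W = "worms/m^2", O = "oxygen fraction"),
               container = "rds")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a field snapshot written by [write_snapshot()]
#'
#' @param path Snapshot path; the `<path>.json` sidecar must exist.
#' @return A `field_state`.
#' @export
read_snapshot <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar `", sidecar,
         "`: refusing to guess grid and units", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  arrays <- readRDS(path)
  if (!identical(dim(arrays$W), as.integer(meta$shape))) {
    stop("array shape does not match sidecar metadata", call. = FALSE)
  }
  new_field_state(as.numeric(meta$t_s), arrays$W, arrays$O,
                  grid2d(meta$N, meta$L_m))
}

#' Export a field as tidy CSV
#'
#' Long format, one cell per row, columns `i`, `j`, `x_m`, `y_m`, `value`,
#' ordered column-major (`j` varies slowest). Cell centres are at
#' `(i - 0.5) dx`.
#'
#' @param field Numeric matrix.
#' @param grid A [grid2d()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, grid, path) {
  stopifnot(is.matrix(field), inherits(grid, "grid2d"))
  N <- nrow(field)
  df <- tibble::tibble(i = rep(seq_len(N), ncol(field)),
                       j = rep(seq_len(ncol(field)), each = N),
                       value = as.vector(field))
  df$x_m <- (df$i - 0.5) * grid$dx
  df$y_m <- (df$j - 0.5) * grid$dx
  utils::write.csv(df[, c("i", "j", "x_m", "y_m", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full trajectory with run manifest
#'
#' Writes numbered snapshots plus a `manifest.json` recording the complete
#' parameter set (with units), grid, seeds, RNG kind, timestamps, package
#' version and a content hash of the configuration, so any two runs with
#' identical manifests are reproducibly identical.
#'
#' @param trajectory An `aeropattern_trajectory`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "aeropattern_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(trajectory$states)) {
    write_snapshot(trajectory$states[[i]],
                   file.path(dir, sprintf("snapshot_%04d.rds", i - 1L)))
  }
  cfg <- c(if (!is.null(trajectory$params)) params_as_list(trajectory$params),
           trajectory$config)
  manifest <- list(parameters = cfg,
                   grid = list(N = trajectory$grid$N, L_m = trajectory$grid$L),
                   times_s = trajectory$times,
                   n_snapshots = length(trajectory$states),
                   rng_kind = trajectory$config$rng_kind %||% "Mersenne-Twister",
                   clamp_log = trajectory$clamp_log,
                   package_version = as.character(utils::packageVersion("aeropattern")),
                   written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config_hash = content_hash(cfg))
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
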