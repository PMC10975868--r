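# End-to-end analysis: raw recording -> conditioned signal -> RMS envelope ->
# bounds envelope -> exercise window -> cycles -> per-individual metrics.

#' Default pipeline configuration
#'
#' Flat list of every tunable the pipeline exposes, with the defaults used
#' throughout the documentation:
#' \describe{
#'   \item{rms_window_s}{Sliding RMS window, 0.1 s (common sEMG practice).}
#'   \item{tc_hat_prior_s}{Prior expected cycle time used to size the bounds
#'     smoothing window before cycles are known, 2.0 s.}
#'   \item{split_smooth_s}{Centered smoothing ahead of trough detection, 0.2 s.}
#'   \item{bounds_threshold_frac}{Exercise-window threshold, 0.1 of max.}
#'   \item{refine_threshold_frac}{Onset/offset threshold for sharpening the
#'     bounds on the RMS envelope, 0.05 of max. Lower than the window
#'     threshold: the coarse threshold measures *sustained* activity on a
#'     two-cycle average, the refinement looks for the first/last
#'     contraction inside the window it found.}
#'   \item{min_prominence_frac}{Cycle-trough prominence threshold, 0.3.}
#'   \item{ereg_degree}{Energy-trend polynomial degree, 2.}
#'   \item{overlay_points}{Points per cycle in the normalized overlay, 100.}
#'   \item{trend_method}{`"ols"` or `"lad"` for the rhythm-drift line.}
#'   \item{peak_rel_height}{Per-cycle peak prominence threshold, 0.3.}
#'   \item{bandpass}{`enabled`, `low_hz`, `high_hz`, `notch_hz` for the raw
#'     signal conditioning stage (20-400 Hz pass, 50 Hz notch).}
#'   \item{channel_map}{Role-to-column mapping used when reading files.}
#' }
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    rms_window_s = 0.1,
    tc_hat_prior_s = 2.0,
    split_smooth_s = 0.2,
    bounds_threshold_frac = 0.1,
    refine_threshold_frac = 0.05,
    min_prominence_frac = 0.3,
    ereg_degree = 2,
    overlay_points = 100,
    trend_method = "ols",
    peak_rel_height = 0.3,
    bandpass = list(enabled = TRUE, low_hz = 20, high_hz = 400, notch_hz = 50),
    channel_map = list(quadriceps = "quadriceps", biceps = "biceps")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of configuration keys and merges it over
#' [default_config()]; keys absent from the file keep their defaults, nested
#' keys (`bandpass`, `channel_map`) merge element-wise.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_rowemg("config", "no such config file: %s", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop_rowemg("config", "config must be a YAML mapping")
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  frac_keys <- c("bounds_threshold_frac", "refine_threshold_frac",
                 "min_prominence_frac", "peak_rel_height")
  for (k in frac_keys) {
    v <- cfg[[k]]
    if (!is_number(v) || v <= 0 || v >= 1)
      stop_rowemg("config", "%s must be a number in (0, 1)", k)
  }
  for (k in c("rms_window_s", "tc_hat_prior_s", "split_smooth_s")) {
    if (!is_number(cfg[[k]]) || cfg[[k]] <= 0)
      stop_rowemg("config", "%s must be a positive number", k)
  }
  if (!cfg$trend_method %in% c("ols", "lad"))
    stop_rowemg("config", "trend_method must be 'ols' or 'lad'")
  invisible(cfg)
}

#' Run the full analysis pipeline on one recording
#'
#' Stages: optional band-pass/notch conditioning; sliding RMS envelope per
#' muscle; heavy (two-cycle) moving average with group-delay compensation for
#' exercise-window detection; bound refinement on the lightly smoothed RMS
#' envelope; trough-prominence cycle segmentation on the quadriceps (the
#' stroke-driving muscle — its boundaries also slice the biceps); then every
#' per-individual metric and the assembled [metrics_report()].
#'
#' A missing biceps channel is tolerated: the report simply omits the
#' activation-order section (with a warning).
#'
#' @param rec An [emg_recording] with at least a `quadriceps` channel.
#' @param config Configuration list, see [default_config()].
#' @return Object of class `emg_analysis`: `report` (a [metrics_report]),
#'   `bounds`, per-muscle `cycles`, and normalized `overlays`.
#' @export
analyze_recording <- function(rec, config = default_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  validate_config(config)
  if (!("quadriceps" %in% names(rec$channels)))
    stop_rowemg("config", "recording lacks the required 'quadriceps' channel")
  fs <- rec$fs
  muscles <- intersect(c("quadriceps", "biceps"), names(rec$channels))

  envs <- lapply(muscles, function(m) {
    raw <- rec$channels[[m]]
    if (isTRUE(config$bandpass$enabled))
      raw <- bandpass_condition(raw, fs, config$bandpass$low_hz,
                                config$bandpass$high_hz, config$bandpass$notch_hz)
    x <- rms_envelope(raw, fs, config$rms_window_s, source_role = m)
    smooth_for_cycles(x, config$split_smooth_s)
  })
  names(envs) <- muscles

  # exercise window: coarse on the two-cycle average, refined on the RMS envelope
  Nw <- choose_ma_window(config$tc_hat_prior_s, fs)
  y_bounds <- smooth_for_bounds(envs$quadriceps, Nw)
  coarse <- detect_bounds(y_bounds, config$bounds_threshold_frac)
  bounds <- refine_bounds(coarse, envs$quadriceps, config$refine_threshold_frac)

  cycles <- list(quadriceps = split_cycles(envs$quadriceps, bounds,
                                           config$min_prominence_frac))
  if ("biceps" %in% muscles)
    cycles$biceps <- slice_cycles(envs$biceps, cycles$quadriceps)

  stats <- cycle_time_stats(cycles$quadriceps)
  trend <- fit_cycle_trend(cycles$quadriceps$tc, method = config$trend_method)

  end_times <- cycles$quadriceps$boundaries[-1] - bounds$a
  energy <- lapply(cycles, function(cs)
    fatigue_point(muscle_energy(cs), end_times, bounds$tt,
                  degree = config$ereg_degree))
  peaks <- lapply(cycles, cycle_peaks, rel_height_frac = config$peak_rel_height)

  phase <- NULL
  if ("biceps" %in% muscles) {
    phase <- phase_order(cycles$quadriceps, cycles$biceps,
                         rel_height_frac = config$peak_rel_height)
  } else {
    warning("no biceps channel: activation-order section omitted from report")
  }
  phases <- if (cycles$quadriceps$n_cycles >= 3L)
    three_phase_split(cycles$quadriceps)

  report <- build_report(rec$subject_id, rec$group, bounds, cycles$quadriceps,
                         stats, trend, energy, peaks, phase, phases)
  overlays <- lapply(cycles, normalize_cycles, n_points = config$overlay_points)

  structure(list(report = report, bounds = bounds, cycles = cycles,
                 overlays = overlays, config = config),
            class = "emg_analysis")
}

#' @export
print.emg_analysis <- function(x, ...) {
  print(x$report)
  invisible(x)
}
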