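# Raw sEMG -> smoothed activation envelope.
#
# Stages: optional zero-phase band-pass + power-line notch, sliding RMS,
# and a trailing moving average whose window is tied to the expected cycle
# time (Nw >= 2 * tc_hat * fs) for exercise-bounds detection.

#' Construct an activation envelope
#'
#' @param samples Nonnegative numeric vector (envelope samples).
#' @param fs Sampling rate in Hz.
#' @param rms_window_s RMS window length in seconds used to produce it
#'   (`NA` if not applicable).
#' @param ma_window_samples Moving-average window in samples (`NA` if the
#'   envelope has not been smoothed).
#' @param source_role Muscle role the envelope was derived from.
#' @return An object of class `emg_envelope`.
#' @export
emg_envelope <- function(samples, fs, rms_window_s = NA_real_,
                         ma_window_samples = NA_integer_,
                         source_role = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_rowemg("parameter", "envelope needs a numeric vector of length >= 2")
  if (any(!is.finite(samples)) || any(samples < 0))
    stop_rowemg("parameter", "envelope samples must be finite and nonnegative")
  if (!is.na(ma_window_samples) && ma_window_samples < 1L)
    stop_rowemg("parameter", "ma_window_samples must be >= 1")
  structure(list(samples = samples, fs = fs, rms_window_s = rms_window_s,
                 ma_window_samples = ma_window_samples, source_role = source_role),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %s: %d samples @ %g Hz (rms %.3g s, ma %s samples)\n",
              x$source_role, length(x$samples), x$fs, x$rms_window_s,
              ifelse(is.na(x$ma_window_samples), "-", x$ma_window_samples)))
  invisible(x)
}

#' Band-pass and notch preconditioning
#'
#' Zero-phase (forward-backward) Butterworth band-pass plus an optional
#' narrow band-stop at the power-line frequency. The high-pass edge removes
#' movement artefacts and electrode drift; the low-pass edge removes
#' out-of-band device noise (sEMG power is concentrated below ~400 Hz).
#'
#' @param raw Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Pass-band edges in Hz (`0 < low < high < fs/2`).
#' @param notch_hz Power-line frequency to suppress (50 or 60; `NA` disables).
#' @param order Butterworth order per edge (default 4).
#' @return Conditioned sample vector, same length as `raw`.
#' @export
bandpass_condition <- function(raw, fs, low_hz = 20, high_hz = 400,
                               notch_hz = 50, order = 4) {
  if (!is_number(fs) || fs <= 0) stop_rowemg("parameter", "fs must be positive")
  if (!(low_hz > 0 && low_hz < high_hz))
    stop_rowemg("parameter", "need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop_rowemg("parameter", "high_hz (%g) must be below Nyquist (%g)", high_hz, fs / 2)
  bp <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, raw)
  if (!is.null(notch_hz) && !is.na(notch_hz)) {
    if (notch_hz >= fs / 2)
      stop_rowemg("parameter", "notch_hz must be below Nyquist")
    bs <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2), type = "stop")
    y <- signal::filtfilt(bs, y)
  }
  y
}

#' Sliding-window RMS envelope
#'
#' Sample `n` of the envelope is the root of the mean of squared raw samples
#' in a centered window of `round(window_s * fs)` samples; windows are
#' truncated at the signal edges.
#'
#' @param raw Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param window_s RMS window in seconds (default 0.1 s, common sEMG practice).
#' @param source_role Muscle role label carried on the result.
#' @return An [emg_envelope].
#' @export
rms_envelope <- function(raw, fs, window_s = 0.1, source_role = NA_character_) {
  w <- as.integer(round(window_s * fs))
  if (!is_number(window_s) || window_s <= 0 || w < 1L)
    stop_rowemg("parameter", "window_s * fs must round to at least 1 sample")
  n <- length(raw)
  if (w > n) stop_rowemg("parameter", "RMS window (%d) longer than signal (%d)", w, n)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(raw^2))
  idx <- seq_len(n)
  lo <- pmax(idx - hl, 1L)
  hi <- pmin(idx + hr, n)
  env <- sqrt(pmax((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), 0))
  emg_envelope(env, fs, rms_window_s = window_s, source_role = source_role)
}

#' Trailing moving average
#'
#' `y(n) = mean(x(n - Nw + 1), ..., x(n))`: a causal window of `Nw` samples.
#' The first `Nw - 1` outputs average over the available prefix only, so the
#' output has the same length as the input.
#'
#' @param x Numeric sample vector.
#' @param Nw Window length in samples (>= 1).
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, Nw) {
  Nw <- as.integer(Nw)
  if (is.na(Nw) || Nw < 1L) stop_rowemg("parameter", "Nw must be >= 1")
  if (Nw == 1L) return(as.numeric(x))
  n <- length(x)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  start <- pmax(idx - Nw + 1L, 1L)
  (cs[idx + 1L] - cs[start]) / (idx - start + 1L)
}

#' Moving-average window rule for bounds detection
#'
#' The smoothing window must cover at least two expected cycles so that
#' intra-cycle relaxations do not pull the envelope below the exercise
#' detection threshold: `Nw = ceil(2 * tc_hat_s * fs)`.
#'
#' @param tc_hat_s Expected (prior) cycle time in seconds.
#' @param fs Sampling rate in Hz.
#' @return Window length in samples (at least 1).
#' @export
choose_ma_window <- function(tc_hat_s, fs) {
  if (!is_number(tc_hat_s) || tc_hat_s <= 0)
    stop_rowemg("parameter", "tc_hat_s must be positive")
  max(1L, as.integer(ceiling(2 * tc_hat_s * fs)))
}

#' Smooth an envelope for exercise-bounds detection
#'
#' Applies the trailing moving average of [moving_average()] and, by default,
#' compensates its group delay of `(Nw - 1) / 2` samples by advancing the
#' output (holding the final value at the tail). The trailing form follows
#' the causal definition of the filter; without compensation the smoothed
#' envelope — and every threshold crossing on it — lags the activity by about
#' one cycle time.
#'
#' @param env An [emg_envelope].
#' @param Nw Window length in samples, e.g. from [choose_ma_window()].
#' @param compensate_delay Advance the output by the filter group delay
#'   (default `TRUE`).
#' @return A smoothed [emg_envelope] with `ma_window_samples` set.
#' @export
smooth_for_bounds <- function(env, Nw, compensate_delay = TRUE) {
  stopifnot(inherits(env, "emg_envelope"))
  y <- moving_average(env$samples, Nw)
  if (compensate_delay && Nw > 1L) {
    k <- (as.integer(Nw) - 1L) %/% 2L
    n <- length(y)
    if (k > 0L && k < n) y <- c(y[(k + 1L):n], rep(y[n], k))
  }
  emg_envelope(y, env$fs, rms_window_s = env$rms_window_s,
               ma_window_samples = as.integer(Nw), source_role = env$source_role)
}

#' Centered moving-average smoothing for cycle segmentation
#'
#' A light zero-phase smoother applied to the RMS envelope before trough
#' detection: it suppresses within-relaxation noise without shifting trough
#' positions (a symmetric window has no group delay). Edge windows are
#' truncated.
#'
#' @param env An [emg_envelope].
#' @param window_s Smoothing window in seconds (default 0.2 s).
#' @return A smoothed [emg_envelope].
#' @export
smooth_for_cycles <- function(env, window_s = 0.2) {
  stopifnot(inherits(env, "emg_envelope"))
  w <- max(1L, as.integer(round(window_s * env$fs)))
  x <- env$samples
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(idx - hl, 1L)
  hi <- pmin(idx + hr, n)
  y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  emg_envelope(y, env$fs, rms_window_s = env$rms_window_s,
               ma_window_samples = w, source_role = env$source_role)
}
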