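# Exercise-window detection and stroke-cycle segmentation.
#
# Bounds: first samples left/right of the global envelope maximum where the
# smoothed envelope drops below a fraction (default 0.1) of its maximum.
# Cycles: interior envelope minima whose topographic prominence, computed on
# the max-normalized envelope, reaches a threshold (default 0.3).

# ---- topographic extrema machinery ------------------------------------------

# Collapse equal-valued plateau runs; each run is represented by its midpoint
# sample ("ties broken toward fewer minima": one candidate per plateau).
compress_runs <- function(z) {
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(val = r$values, idx = (starts + ends) %/% 2L)
}

# Alternating extrema of z, with window endpoints included as nodes. Between
# consecutive nodes the signal is monotone, so all prominence bookkeeping can
# run on this (much shorter) node sequence.
extrema_nodes <- function(z) {
  cr <- compress_runs(z)
  v <- cr$val
  k <- length(v)
  if (k < 3L) {
    return(list(idx = cr$idx, val = v, kind = rep("end", k)))
  }
  i <- 2:(k - 1L)
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  keep <- which(is_min | is_max) + 1L
  kind <- c("end", ifelse(is_min, "min", "max")[keep - 1L], "end")
  sel <- c(1L, keep, k)
  list(idx = cr$idx[sel], val = v[sel], kind = kind)
}

# Topographic prominence of each interior trough of z: on the inverted signal,
# descend from the trough on each side until a deeper trough (higher inverted
# value) or the window edge is reached; the base on that side is the lowest
# point passed. Prominence = trough depth above the higher of the two bases.
trough_prominences <- function(z) {
  nodes <- extrema_nodes(z)
  iv <- -nodes$val
  cand <- which(nodes$kind == "min")
  if (length(cand) == 0L)
    return(data.frame(idx = integer(), prominence = numeric()))
  prom <- vapply(cand, function(j) {
    h <- iv[j]
    base_l <- Inf
    for (t in seq(j - 1L, 1L)) {
      if (iv[t] > h) break
      base_l <- min(base_l, iv[t])
    }
    base_r <- Inf
    for (t in seq(j + 1L, length(iv))) {
      if (iv[t] > h) break
      base_r <- min(base_r, iv[t])
    }
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(idx = nodes$idx[cand], prominence = prom)
}

# ---- exercise bounds --------------------------------------------------------

#' Construct exercise bounds
#'
#' @param a,b Start and end of the exercise in seconds; `tt = b - a` exactly.
#' @param fs Sampling rate in Hz.
#' @param a_index,b_index 1-based sample indices of `a` and `b`.
#' @param threshold_frac Detection threshold used, as a fraction of the
#'   envelope maximum.
#' @return An object of class `exercise_bounds`.
#' @export
exercise_bounds <- function(a, b, fs, a_index, b_index, threshold_frac = NA_real_) {
  if (!(a < b)) stop_rowemg("parameter", "need a < b (got a=%g, b=%g)", a, b)
  structure(list(a = a, b = b, tt = b - a, fs = fs,
                 a_index = as.integer(a_index), b_index = as.integer(b_index),
                 threshold_frac = threshold_frac),
            class = "exercise_bounds")
}

#' @export
print.exercise_bounds <- function(x, ...) {
  cat(sprintf("<exercise_bounds> a=%.3f s, b=%.3f s, tt=%.3f s\n", x$a, x$b, x$tt))
  invisible(x)
}

#' Detect the exercise window on a smoothed envelope
#'
#' Starting from the global maximum of the envelope, the bounds are the last
#' samples on each side whose value is still at or above
#' `threshold_frac * max(y)`; equivalently, one sample inside the first
#' crossings below the threshold. A side with no crossing is bounded by the
#' signal edge. An all-zero envelope, or one that never drops below the
#' threshold on either side (no distinguishable activity window), raises a
#' no-exercise error.
#'
#' @param env An [emg_envelope] (typically from [smooth_for_bounds()]).
#' @param threshold_frac Fraction of the envelope maximum (default 0.1).
#' @return An [exercise_bounds].
#' @export
detect_bounds <- function(env, threshold_frac = 0.1) {
  stopifnot(inherits(env, "emg_envelope"))
  if (!(threshold_frac > 0 && threshold_frac < 1))
    stop_rowemg("parameter", "threshold_frac must be in (0, 1)")
  y <- env$samples
  n <- length(y)
  ymax <- max(y)
  if (ymax <= 0) stop_rowemg("noexercise", "envelope is identically zero")
  thr <- threshold_frac * ymax
  im <- which.max(y)

  below_l <- if (im > 1L) which(y[seq_len(im - 1L)] < thr) else integer()
  below_r <- if (im < n) which(y[(im + 1L):n] < thr) + im else integer()
  if (length(below_l) == 0L && length(below_r) == 0L)
    stop_rowemg("noexercise", "envelope never drops below %.3g of its maximum", threshold_frac)
  a_idx <- if (length(below_l)) max(below_l) + 1L else 1L
  b_idx <- if (length(below_r)) min(below_r) - 1L else n

  exercise_bounds((a_idx - 1L) / env$fs, (b_idx - 1L) / env$fs, env$fs,
                  a_idx, b_idx, threshold_frac)
}

#' Refine exercise bounds on the RMS envelope
#'
#' The heavily smoothed envelope locates the activity window robustly (single
#' isolated contractions before/after the exercise cannot trigger it) but its
#' window-length ramps blur the edges by a sizeable fraction of the smoothing
#' window. This step sharpens the bounds: within the coarse window it finds
#' the first and last samples of the fast (RMS) envelope at or above
#' `threshold_frac` of that window's maximum. The default threshold is lower
#' than the coarse one because it looks for the onset/offset of individual
#' contractions rather than sustained activity.
#'
#' @param coarse An [exercise_bounds] from [detect_bounds()].
#' @param env The fast envelope (RMS, lightly smoothed) on the same grid.
#' @param threshold_frac Fraction of the in-window maximum (default 0.05).
#' @return A refined [exercise_bounds].
#' @export
refine_bounds <- function(coarse, env, threshold_frac = 0.05) {
  stopifnot(inherits(coarse, "exercise_bounds"), inherits(env, "emg_envelope"))
  x <- env$samples[coarse$a_index:coarse$b_index]
  m <- max(x)
  if (m <= 0) stop_rowemg("noexercise", "no activity inside the coarse window")
  keep <- which(x >= threshold_frac * m)
  a_idx <- coarse$a_index + min(keep) - 1L
  b_idx <- coarse$a_index + max(keep) - 1L
  if (b_idx <= a_idx) stop_rowemg("noexercise", "degenerate refined window")
  exercise_bounds((a_idx - 1L) / env$fs, (b_idx - 1L) / env$fs, env$fs,
                  a_idx, b_idx, threshold_frac)
}

# ---- cycle segmentation -----------------------------------------------------

#' Construct a cycle set
#'
#' Internal constructor shared by [split_cycles()] and [slice_cycles()].
#' Segments are stored inclusive of both boundary samples (the shared trough
#' sample bridges adjacent segments) so that per-cycle trapezoidal energies
#' add up exactly to the whole-window integral; cycle *ownership* of the
#' boundary sample is half-open (a trough belongs to the following cycle).
#'
#' @param env Envelope the segments are sliced from.
#' @param boundary_idx 1-based sample indices of the segment boundaries,
#'   including the exercise start and end.
#' @return An object of class `cycle_set`.
#' @keywords internal
new_cycle_set <- function(env, boundary_idx) {
  fs <- env$fs
  k <- length(boundary_idx)
  if (k < 2L) stop_rowemg("parameter", "need at least two boundaries")
  times <- (boundary_idx - 1L) / fs
  segments <- lapply(seq_len(k - 1L), function(i)
    env$samples[boundary_idx[i]:boundary_idx[i + 1L]])
  structure(list(
    boundaries = times, boundary_idx = as.integer(boundary_idx),
    segments = segments, tc = diff(times),
    n_cycles = k - 1L, fs = fs, source_role = env$source_role
  ), class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %s: Nc=%d, t in [%.2f, %.2f] s, t_bar=%.3f s\n",
              x$source_role, x$n_cycles, x$boundaries[1],
              x$boundaries[length(x$boundaries)], mean(x$tc)))
  invisible(x)
}

#' Split the exercise window into stroke cycles
#'
#' Cycle boundaries are the interior local minima of the envelope inside the
#' exercise window whose trough prominence, computed on the envelope
#' normalized by its in-window maximum, is at least `min_prominence_frac`.
#' Flat troughs contribute their midpoint sample. With no qualifying minima
#' the window is a single cycle.
#'
#' @param env An [emg_envelope] that still carries cycle structure (the RMS
#'   envelope, optionally lightly smoothed — not the bounds envelope).
#' @param bounds An [exercise_bounds] on the same sample grid.
#' @param min_prominence_frac Minimum trough prominence as a fraction of the
#'   envelope maximum (default 0.3).
#' @return A `cycle_set`; its `tc` durations sum to `bounds$tt` exactly.
#' @export
split_cycles <- function(env, bounds, min_prominence_frac = 0.3) {
  stopifnot(inherits(env, "emg_envelope"), inherits(bounds, "exercise_bounds"))
  if (!(min_prominence_frac > 0 && min_prominence_frac < 1))
    stop_rowemg("parameter", "min_prominence_frac must be in (0, 1)")
  ai <- bounds$a_index
  bi <- bounds$b_index
  if (bi - ai < 1L) stop_rowemg("parameter", "empty exercise window")
  w <- env$samples[ai:bi]
  wmax <- max(w)
  if (wmax <= 0) stop_rowemg("noexercise", "no activity inside the exercise window")
  tr <- trough_prominences(w / wmax)
  keep <- tr$idx[tr$prominence >= min_prominence_frac]
  keep <- keep[keep > 1L & keep < length(w)]
  new_cycle_set(env, c(ai, ai + sort(keep) - 1L, bi))
}

#' Slice an envelope on boundaries taken from another muscle
#'
#' The quadriceps drives the stroke, so its trough boundaries define the
#' cycles; the biceps envelope is sliced on the same boundaries so per-cycle
#' comparisons (activation order) line up.
#'
#' @param env An [emg_envelope] on the same sample grid.
#' @param cs A `cycle_set` providing the boundaries.
#' @return A `cycle_set` over `env` with identical boundaries.
#' @export
slice_cycles <- function(env, cs) {
  stopifnot(inherits(env, "emg_envelope"), inherits(cs, "cycle_set"))
  if (max(cs$boundary_idx) > length(env$samples))
    stop_rowemg("parameter", "boundaries exceed envelope length")
  if (!isTRUE(all.equal(env$fs, cs$fs)))
    stop_rowemg("parameter", "sampling rates differ between envelope and cycle set")
  new_cycle_set(env, cs$boundary_idx)
}

#' Flag suspiciously long or short cycles
#'
#' Misplaced minima typically produce durations near an integer multiple
#' (missed boundary) or near half (spurious boundary) of the typical cycle
#' time. Cycles whose duration lies within `tol` (relative) of `k * t_bar`
#' for integer `k >= 2`, or of `0.5 * t_bar`, are flagged. Informational
#' only; the cycle set is not modified.
#'
#' @param cs A `cycle_set` with at least two cycles.
#' @param t_bar Reference cycle time in seconds; defaults to the median
#'   duration (robust against the very outliers being flagged).
#' @param tol Relative tolerance (default 0.15).
#' @return Integer vector of flagged cycle indices (possibly empty).
#' @export
validate_cycles <- function(cs, t_bar = stats::median(cs$tc), tol = 0.15) {
  stopifnot(inherits(cs, "cycle_set"))
  if (cs$n_cycles < 2L) stop_rowemg("parameter", "need at least 2 cycles to validate")
  kmax <- max(2, ceiling(max(cs$tc) / t_bar))
  refs <- c(0.5, seq(2, kmax)) * t_bar
  flagged <- vapply(cs$tc, function(d) any(abs(d - refs) / refs <= tol), logical(1))
  which(flagged)
}
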