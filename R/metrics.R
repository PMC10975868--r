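# Per-individual performance parameters: cycle-time statistics, rhythm-drift
# regression, per-cycle muscle energy and the polynomial-trend fatigue point,
# activation peaks and quadriceps/biceps ordering, overlay normalization, and
# the warm-up / exercise / fatigue three-way split.

#' Cycle-time mean and standard deviation
#'
#' The standard deviation uses the sample (`Nc - 1`) denominator; it measures
#' how well the individual kept the stroke rhythm.
#'
#' @param cs A `cycle_set` with at least two cycles.
#' @return List with `t_bar` and `sigma`, both in seconds.
#' @export
cycle_time_stats <- function(cs) {
  stopifnot(inherits(cs, "cycle_set"))
  if (cs$n_cycles < 2L)
    stop_rowemg("insufficient", "sigma needs at least 2 cycles (got %d)", cs$n_cycles)
  list(t_bar = mean(cs$tc), sigma = stats::sd(cs$tc))
}

#' Rhythm-drift regression over cycle durations
#'
#' Fits `tc[i] ~ a_hat * i + b_hat` over cycle index `i = 1..Nc`. A positive
#' slope means strokes are slowing down as the exercise progresses. The
#' default fit is ordinary least squares; `method = "lad"` minimizes the sum
#' of absolute errors instead (iteratively reweighted least squares).
#'
#' @param tc Numeric vector of cycle durations (seconds), or a `cycle_set`.
#' @param method `"ols"` (default) or `"lad"`.
#' @return List of class `cycle_trend` with `a_hat` (s/cycle), `b_hat` (s),
#'   `residuals`, and `method`.
#' @export
fit_cycle_trend <- function(tc, method = c("ols", "lad")) {
  method <- match.arg(method)
  if (inherits(tc, "cycle_set")) tc <- tc$tc
  n <- length(tc)
  if (n < 2L) stop_rowemg("insufficient", "trend needs at least 2 cycles")
  i <- seq_len(n)
  if (method == "ols") {
    fit <- stats::lm(tc ~ i)
    co <- stats::coef(fit)
  } else {
    co <- stats::coef(stats::lm(tc ~ i))
    for (iter in seq_len(50)) {
      r <- tc - (co[1] + co[2] * i)
      w <- 1 / pmax(abs(r), 1e-8)
      co_new <- stats::coef(stats::lm(tc ~ i, weights = w))
      if (max(abs(co_new - co)) < 1e-12) break
      co <- co_new
    }
  }
  structure(list(a_hat = unname(co[2]), b_hat = unname(co[1]),
                 residuals = unname(tc - (co[1] + co[2] * i)), method = method),
            class = "cycle_trend")
}

#' Per-cycle muscle energy
#'
#' Energy of cycle `i` is the integral of its envelope segment over the cycle
#' duration (trapezoidal rule), in \eqn{\mu}V s. It is an effort proxy that
#' is comparable only within one individual — raw sEMG amplitude depends on
#' electrode placement and physiology.
#'
#' @param cs A `cycle_set`.
#' @return Numeric vector of per-cycle energies.
#' @export
muscle_energy <- function(cs) {
  stopifnot(inherits(cs, "cycle_set"))
  vapply(cs$segments, function(seg) {
    if (length(seg) < 2L) stop_rowemg("parameter", "empty cycle segment")
    pracma::trapz((seq_along(seg) - 1) / cs$fs, seg)
  }, numeric(1))
}

#' Fatigue point from the per-cycle energy trend
#'
#' Fits a polynomial (default degree 2) to per-cycle energies against cycle
#' end time and locates the maximum of the fitted curve on `[0, tt]`. The
#' fatigue percentage is the share of the exercise performed after that
#' maximum: `100 * (tt - t_peak) / tt`. When the fitted maximum falls at or
#' beyond the end of the exercise the individual never entered the fatigue
#' phase and the result is exactly 0%.
#'
#' @param em Per-cycle energies (\eqn{\mu}V s).
#' @param cycle_end_times Cycle end times in seconds, measured from exercise
#'   start.
#' @param tt Training time in seconds.
#' @param degree Polynomial degree (default 2: one interior maximum).
#' @return List of class `energy_profile`: `em`, `coefficients` (ascending
#'   powers), `t_peak` (s), `fatigue_pct`.
#' @export
fatigue_point <- function(em, cycle_end_times, tt, degree = 2) {
  n <- length(em)
  if (length(cycle_end_times) != n)
    stop_rowemg("parameter", "em and cycle_end_times lengths differ")
  if (n < degree + 1)
    stop_rowemg("insufficient", "degree-%d fit needs at least %d cycles (got %d)",
                degree, degree + 1, n)
  tme <- cycle_end_times
  fit <- stats::lm(em ~ stats::poly(tme, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))            # ascending powers 0..degree
  beta[is.na(beta)] <- 0
  dcoef <- beta[-1] * seq_len(degree)         # derivative, ascending powers
  while (length(dcoef) > 0 && dcoef[length(dcoef)] == 0)
    dcoef <- dcoef[-length(dcoef)]            # polyroot needs a nonzero lead
  crit <- numeric()
  if (length(dcoef) > 1) {
    rts <- polyroot(dcoef)
    crit <- Re(rts[abs(Im(rts)) < 1e-8])
    crit <- crit[crit > 0 & crit < tt]
  }
  cand <- unique(c(0, crit, tt))
  vals <- vapply(cand, function(t0) sum(beta * t0^(0:degree)), numeric(1))
  t_peak <- cand[which.max(vals)]
  fatigue_pct <- max(0, 100 * (tt - t_peak) / tt)
  structure(list(em = em, coefficients = beta, degree = degree,
                 t_peak = t_peak, fatigue_pct = fatigue_pct),
            class = "energy_profile")
}

#' Per-cycle activation peaks
#'
#' Local maxima of each cycle's envelope segment with topographic prominence
#' of at least `rel_height_frac` times the segment maximum. A clean stroke
#' has one principal activation peak per muscle; a second peak signals a
#' repeated (corrective) activation. Times are relative to the cycle start.
#'
#' @param cs A `cycle_set`.
#' @param rel_height_frac Prominence threshold as a fraction of the segment
#'   maximum (default 0.3).
#' @return List of class `cycle_peaks`: per-cycle data frames (`time`,
#'   `prominence`), vector `n_peaks`, and `principal_time` (time of the most
#'   prominent peak, `NA` when a cycle has none).
#' @export
cycle_peaks <- function(cs, rel_height_frac = 0.3) {
  stopifnot(inherits(cs, "cycle_set"))
  per_cycle <- lapply(cs$segments, function(seg) {
    smax <- max(seg)
    if (smax <= 0)
      return(data.frame(time = numeric(), prominence = numeric()))
    pk <- trough_prominences(-seg / smax)  # peaks of seg are troughs of -seg
    pk <- pk[pk$prominence >= rel_height_frac, , drop = FALSE]
    data.frame(time = (pk$idx - 1) / cs$fs,
               prominence = pk$prominence * smax)
  })
  n_peaks <- vapply(per_cycle, nrow, integer(1))
  principal <- vapply(seq_along(per_cycle), function(i) {
    p <- per_cycle[[i]]
    if (nrow(p) == 0L) return(NA_real_)
    best <- order(-p$prominence, p$time)[1]
    p$time[best]
  }, numeric(1))
  structure(list(per_cycle = per_cycle, n_peaks = n_peaks,
                 principal_time = principal, rel_height_frac = rel_height_frac),
            class = "cycle_peaks")
}

#' Activation-order check between quadriceps and biceps
#'
#' A correctly executed stroke drives with the legs first: within each cycle
#' the principal biceps activation must not precede the principal quadriceps
#' activation. Both cycle sets must share the same boundaries (slice the
#' biceps envelope with [slice_cycles()] on the quadriceps boundaries).
#'
#' @param quad,biceps `cycle_set` objects with identical boundaries.
#' @param rel_height_frac Peak prominence threshold passed to [cycle_peaks()].
#' @return List of class `phase_order_result`: per-cycle data frame
#'   (`quad_time`, `biceps_time`, `n_peaks_quad`, `n_peaks_biceps`,
#'   `order_ok`) and the total `violations` count. Cycles lacking a peak in
#'   either muscle have `order_ok = NA` and are not counted as violations.
#' @export
phase_order <- function(quad, biceps, rel_height_frac = 0.3) {
  stopifnot(inherits(quad, "cycle_set"), inherits(biceps, "cycle_set"))
  if (!identical(quad$boundary_idx, biceps$boundary_idx))
    stop_rowemg("parameter", "cycle boundaries differ between the two muscles")
  pq <- cycle_peaks(quad, rel_height_frac)
  pb <- cycle_peaks(biceps, rel_height_frac)
  ok <- pb$principal_time >= pq$principal_time  # NA when either is NA
  per_cycle <- data.frame(
    cycle = seq_len(quad$n_cycles),
    quad_time = pq$principal_time, biceps_time = pb$principal_time,
    n_peaks_quad = pq$n_peaks, n_peaks_biceps = pb$n_peaks,
    order_ok = ok
  )
  structure(list(per_cycle = per_cycle,
                 violations = sum(!ok, na.rm = TRUE)),
            class = "phase_order_result")
}

#' Phase-normalized cycle overlay
#'
#' Resamples every cycle to a common number of points on a 0..1 phase axis
#' (linear interpolation) and scales amplitudes by the per-individual,
#' per-muscle maximum over all cycles, so the overlay maximum is exactly 1.
#' Raw sEMG amplitudes are not comparable between individuals; normalized
#' overlays are how cycles are compared within one individual.
#'
#' @param x A `cycle_set`, or a list of numeric segment vectors.
#' @param n_points Number of resampled points per cycle (default 100).
#' @return List of class `cycle_overlay`: `phase`, `matrix`
#'   (`Nc x n_points`), and per-point `min`/`mean`/`max` curves.
#' @export
normalize_cycles <- function(x, n_points = 100) {
  UseMethod("normalize_cycles")
}

#' @export
normalize_cycles.cycle_set <- function(x, n_points = 100) {
  normalize_cycles(x$segments, n_points)
}

#' @export
normalize_cycles.list <- function(x, n_points = 100) {
  if (length(x) < 1L || n_points < 2L)
    stop_rowemg("parameter", "need at least 1 cycle and 2 points")
  phase <- seq(0, 1, length.out = n_points)
  mat <- t(vapply(x, function(seg) {
    if (length(seg) < 2L) stop_rowemg("parameter", "empty cycle segment")
    stats::approx(seq(0, 1, length.out = length(seg)), seg, xout = phase)$y
  }, numeric(n_points)))
  m <- max(mat)
  if (m > 0) mat <- mat / m
  structure(list(phase = phase, matrix = mat,
                 min = apply(mat, 2, min), mean = colMeans(mat),
                 max = apply(mat, 2, max)),
            class = "cycle_overlay")
}

#' Split cycles into warm-up, exercise, and fatigue thirds
#'
#' Contiguous index split into three equal groups (0–33%, 33–66%, 66–100% of
#' `Nc`); remainder cycles go to the last (fatigue) group.
#'
#' @param cs A `cycle_set` with at least 3 cycles.
#' @return List of class `phase_split` with integer index vectors `warmup`,
#'   `exercise`, `fatigue` and a `sizes` vector.
#' @export
three_phase_split <- function(cs) {
  stopifnot(inherits(cs, "cycle_set"))
  n <- cs$n_cycles
  if (n < 3L) stop_rowemg("insufficient", "three-way split needs at least 3 cycles")
  base <- n %/% 3L
  idx <- list(warmup = seq_len(base),
              exercise = seq(base + 1L, 2L * base),
              fatigue = seq(2L * base + 1L, n))
  structure(c(idx, list(sizes = vapply(idx, length, integer(1)))),
            class = "phase_split")
}

# ---- assembly ---------------------------------------------------------------

#' Reference values of a well-trained rower
#'
#' Nominal per-individual parameter levels used by the advisory
#' recommendation rules: training time, cycle-time SD, mean cycle time and
#' drift slope typical of a trained athlete on a 500 m piece. Override to
#' recalibrate the advice to a different population.
#'
#' @return Named list with `tt`, `sigma`, `t_bar`, `a_hat`.
#' @export
athlete_reference <- function() {
  list(tt = 83, sigma = 0.072, t_bar = 1.34, a_hat = 0.005)
}

#' Advisory training recommendations
#'
#' Rule-based flags derived from the computed parameters, relative to a
#' reference athlete profile: `"rhythm_work"` when the cycle-time SD is
#' inflated (sigma > 1.5x reference), `"endurance_path"` when fatigue set in
#' early despite a short total time (high strength, poor endurance), and
#' `"strength_path"` when cycles are long but rhythm is stable (high
#' endurance, low power). Advisory output only.
#'
#' @param tt,sigma,t_bar,a_hat,fatigue_pct Computed parameters.
#' @param reference Reference levels, see [athlete_reference()].
#' @return Character vector of zero or more flags.
#' @export
recommend_training <- function(tt, sigma, t_bar, a_hat, fatigue_pct,
                               reference = athlete_reference()) {
  flags <- character()
  if (is.finite(sigma) && sigma > 1.5 * reference$sigma)
    flags <- c(flags, "rhythm_work")
  if (is.finite(fatigue_pct) && fatigue_pct > 25 && tt < 1.2 * reference$tt)
    flags <- c(flags, "endurance_path")
  if (t_bar > 1.5 * reference$t_bar && a_hat < 3 * reference$a_hat)
    flags <- c(flags, "strength_path")
  flags
}

#' Assemble a metrics report from computed components
#'
#' Glue between the individual metric operations and the validated
#' [metrics_report()] container; normally called via [analyze_recording()].
#'
#' @param subject_id,group Subject metadata.
#' @param bounds An [exercise_bounds].
#' @param cycles Master (quadriceps) `cycle_set`.
#' @param stats Output of [cycle_time_stats()].
#' @param trend Output of [fit_cycle_trend()].
#' @param energy Named list of per-muscle [fatigue_point()] profiles; the
#'   `quadriceps` entry provides the headline fatigue percentage.
#' @param peaks Named list of per-muscle [cycle_peaks()] results.
#' @param phase Output of [phase_order()], or `NULL` when no biceps channel
#'   is available.
#' @param phases Output of [three_phase_split()], or `NULL`.
#' @param reference Reference profile for [recommend_training()].
#' @return A [metrics_report].
#' @export
build_report <- function(subject_id, group, bounds, cycles, stats, trend,
                         energy, peaks, phase = NULL, phases = NULL,
                         reference = athlete_reference()) {
  fat <- lapply(energy, function(e) e$fatigue_pct)
  headline <- fat$quadriceps %||% fat[[1]]
  peaks_out <- lapply(peaks, function(p)
    list(n_peaks = p$n_peaks, principal_time_s = p$principal_time))
  phase_out <- if (!is.null(phase))
    list(violations = phase$violations, order_ok = phase$per_cycle$order_ok)
  phases_out <- if (!is.null(phases))
    list(sizes = phases$sizes,
         warmup = range(phases$warmup), exercise = range(phases$exercise),
         fatigue = range(phases$fatigue))
  recommendations <- recommend_training(
    tt = bounds$tt, sigma = stats$sigma, t_bar = stats$t_bar,
    a_hat = trend$a_hat, fatigue_pct = headline, reference = reference
  )
  metrics_report(
    subject_id = subject_id, group = group,
    tt_s = bounds$tt, n_cycles = cycles$n_cycles, tc_s = cycles$tc,
    t_bar_s = stats$t_bar, sigma_s = stats$sigma,
    a_hat_s_per_cycle = trend$a_hat, b_hat_s = trend$b_hat,
    em = lapply(energy, function(e) e$em),
    fatigue_pct = headline, fatigue = fat,
    peaks = peaks_out, phase_order = phase_out, phases = phases_out,
    recommendations = recommendations, fs = bounds$fs
  )
}
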