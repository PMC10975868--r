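# Synthetic two-channel sEMG generator with full ground truth.
#
# Raw signal model: band-limited (20-400 Hz) unit-RMS Gaussian carrier,
# amplitude-modulated by a noiseless activation envelope built from
# per-cycle raised-cosine bursts (quadriceps leading biceps) on top of a low
# tonic component, plus isolated short contractions in the idle regions
# before and after the exercise. Every draw is scoped to an explicit seed.

#' Specify a synthetic rowing recording
#'
#' Parameters define the study conditions a generated recording emulates:
#' idle padding with isolated contraction spikes, a block of stroke cycles
#' with normally distributed durations and a linear drift (the injected
#' rhythm-drift slope), per-muscle burst timing with the biceps lagging the
#' quadriceps, and a rise-then-fall energy profile whose peak position is the
#' injected fatigue point.
#'
#' @param fs Sampling rate in Hz.
#' @param idle_pre_s,idle_post_s Idle durations before/after the exercise (s).
#' @param n_cycles Number of stroke cycles.
#' @param cycle_time_s Base cycle duration (s).
#' @param cycle_time_sd_s SD of cycle durations (s).
#' @param cycle_time_drift_s Linear duration drift per cycle (s/cycle).
#' @param duty_quadriceps,duty_biceps Burst duration as a fraction of the
#'   cycle, in (0, 1).
#' @param biceps_lag_s Biceps burst-peak lag behind the quadriceps peak (s);
#'   negative means the arms fire first (the signature amateur error).
#' @param energy_peak_frac Position of the energy-profile maximum as a
#'   fraction of the exercise, in (0, 1]; 1 means energy still rising at the
#'   end (fatigue 0%).
#' @param burst_amplitude_uV Peak burst amplitude (\eqn{\mu}V).
#' @param tonic_frac Low tonic activation between bursts, as a fraction of
#'   the burst amplitude. Keeps inter-burst relaxation realistic (real
#'   muscle tone never drops to a dead-flat floor) and gives each cycle
#'   boundary a well-defined envelope minimum.
#' @param noise_floor_uV Baseline noise amplitude (\eqn{\mu}V RMS).
#' @param spike_amplitude_uV Amplitude of isolated idle-region contractions.
#' @param n_spikes_pre,n_spikes_post Number of idle spikes on each side.
#' @param subject_id,group Metadata forwarded to the recording.
#' @param seed Default seed used by [generate_recording()].
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(fs = 1000, idle_pre_s = 12, idle_post_s = 12,
                            n_cycles = 40, cycle_time_s = 1.8,
                            cycle_time_sd_s = 0.10, cycle_time_drift_s = 0.008,
                            duty_quadriceps = 0.55, duty_biceps = 0.45,
                            biceps_lag_s = 0.2, energy_peak_frac = 0.7,
                            burst_amplitude_uV = 200, tonic_frac = 0.15,
                            noise_floor_uV = 2, spike_amplitude_uV = 80,
                            n_spikes_pre = 2, n_spikes_post = 1,
                            subject_id = "sim", group = "unknown", seed = 1L) {
  if (fs <= 0 || idle_pre_s <= 0 || idle_post_s <= 0 || cycle_time_s <= 0)
    stop_rowemg("parameter", "durations and fs must be positive")
  if (n_cycles < 1L) stop_rowemg("parameter", "n_cycles must be >= 1")
  if (!(duty_quadriceps > 0 && duty_quadriceps < 1) ||
      !(duty_biceps > 0 && duty_biceps < 1))
    stop_rowemg("parameter", "duty fractions must be in (0, 1)")
  if (!(energy_peak_frac > 0 && energy_peak_frac <= 1))
    stop_rowemg("parameter", "energy_peak_frac must be in (0, 1]")
  if (cycle_time_sd_s < 0 || burst_amplitude_uV < 0 || noise_floor_uV <= 0)
    stop_rowemg("parameter", "negative amplitude or SD")
  structure(as.list(environment()), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d cycles x %.2f s (sd %.2f, drift %+.3f s/cycle), lag %+.2f s, energy peak at %.0f%%\n",
    x$n_cycles, x$cycle_time_s, x$cycle_time_sd_s, x$cycle_time_drift_s,
    x$biceps_lag_s, 100 * x$energy_peak_frac))
  invisible(x)
}

# Raised-cosine bump on [0, 1]: smooth, unimodal, analytic peak at 1/2.
raised_cosine <- function(u) ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)

# Rise-then-fall energy profile over normalized exercise time p in [0, 1]:
# concave quadratic peaking at `pf`, never below 0.5 of its maximum.
energy_profile_g <- function(p, pf) {
  w <- max(pf, 1 - pf)
  1 - 0.5 * ((p - pf) / w)^2
}

# Unit-RMS band-limited Gaussian carrier.
band_noise <- function(n, fs, low = 20, high = 400) {
  bp <- signal::butter(4, c(low, min(high, 0.45 * fs)) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate a synthetic recording with ground truth
#'
#' Deterministic for a fixed seed: the same `(spec, seed)` pair always yields
#' a bit-identical recording. The returned ground truth carries the realized
#' (not nominal) condition values: exercise bounds, cycle boundaries, cycle
#' count and duration statistics, the OLS drift slope of the true durations,
#' per-cycle burst-peak times for both muscles, and the fatigue point implied
#' by the noiseless per-cycle activation energies.
#'
#' True bounds are defined on the noiseless quadriceps activation envelope as
#' the support of values above 5% of its maximum — a method-independent
#' reading of "first contraction to last relaxation" (a smooth envelope
#' touches zero only exactly at the cycle boundary). The true per-cycle
#' durations `tc` are measured within that window, so the first and last
#' cycles are shorter than their nominal draws (`tc_nominal`) and `sum(tc)`
#' equals `tt` exactly.
#'
#' @param spec A [simulation_spec].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `recording` (an [emg_recording]) and `truth` (a list of
#'   ground-truth values).
#' @export
generate_recording <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(as.integer(seed), generate_recording_impl(spec, as.integer(seed)))
}

generate_recording_impl <- function(spec, seed) {
  fs <- spec$fs
  n_cyc <- spec$n_cycles

  # realized cycle durations: base + drift + noise, clipped to sane strokes
  d <- spec$cycle_time_s + spec$cycle_time_drift_s * (seq_len(n_cyc) - 1) +
    stats::rnorm(n_cyc, 0, spec$cycle_time_sd_s)
  d <- pmin(pmax(d, 0.5 * spec$cycle_time_s), 1.8 * spec$cycle_time_s)

  a0 <- spec$idle_pre_s
  tb <- a0 + c(0, cumsum(d))            # cycle boundary times, length n_cyc + 1
  total_s <- a0 + sum(d) + spec$idle_post_s
  n <- as.integer(round(total_s * fs))
  t <- (seq_len(n) - 1) / fs

  # per-cycle amplitudes from the rise-then-fall energy profile
  p_end <- (tb[-1] - a0) / sum(d)
  amp <- spec$burst_amplitude_uV * energy_profile_g(p_end, spec$energy_peak_frac)

  s0_q <- 0.08                          # quadriceps burst start (cycle fraction)
  act_q <- numeric(n)
  act_b <- numeric(n)
  peak_q <- peak_b <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    i0 <- as.integer(floor(tb[i] * fs)) + 1L
    i1 <- min(as.integer(ceiling(tb[i + 1] * fs)) + 1L, n)
    s <- (t[i0:i1] - tb[i]) / d[i]
    s <- pmin(pmax(s, 0), 1)
    tonic <- spec$tonic_frac * sin(pi * s)^2
    uq <- (s - s0_q) / spec$duty_quadriceps
    # biceps burst centered at the quadriceps peak plus the configured lag
    c_b <- s0_q + spec$duty_quadriceps / 2 + spec$biceps_lag_s / d[i]
    s0_b <- min(max(c_b - spec$duty_biceps / 2, 0), 1 - spec$duty_biceps)
    ub <- (s - s0_b) / spec$duty_biceps
    act_q[i0:i1] <- pmax(act_q[i0:i1], amp[i] * (tonic + raised_cosine(uq)))
    act_b[i0:i1] <- pmax(act_b[i0:i1], amp[i] * (tonic + raised_cosine(ub)))
    peak_q[i] <- tb[i] + (s0_q + spec$duty_quadriceps / 2) * d[i]
    peak_b[i] <- tb[i] + (s0_b + spec$duty_biceps / 2) * d[i]
  }

  # isolated contractions in the idle regions, kept clear of the exercise
  add_spikes <- function(act, k, lo, hi) {
    if (k < 1L || hi - lo < 1) return(act)
    centers <- sort(stats::runif(k, lo, hi))
    for (ctr in centers) {
      u <- (t - (ctr - 0.15)) / 0.3
      act <- act + spec$spike_amplitude_uV * raised_cosine(u)
    }
    act
  }
  b0 <- tb[n_cyc + 1]
  act_q <- add_spikes(act_q, spec$n_spikes_pre, 2, a0 - 3)
  act_q <- add_spikes(act_q, spec$n_spikes_post, b0 + 3, total_s - 2)
  act_b <- add_spikes(act_b, spec$n_spikes_pre, 2, a0 - 3)

  channels <- list(
    quadriceps = band_noise(n, fs) * (spec$noise_floor_uV + act_q),
    biceps     = band_noise(n, fs) * (spec$noise_floor_uV + act_b),
    reference  = band_noise(n, fs) * spec$noise_floor_uV
  )
  rec <- emg_recording(fs, channels, subject_id = spec$subject_id, group = spec$group)

  # ground truth -------------------------------------------------------------
  if (max(act_q) > 0) {
    on <- which(act_q > 0.05 * max(act_q))
    # restrict to the exercise block (spikes are separate events, not exercise)
    on <- on[t[on] >= a0 - 1e-9 & t[on] <= b0 + 1e-9]
  } else on <- integer()
  a_true <- if (length(on)) t[min(on)] else NA_real_
  b_true <- if (length(on)) t[max(on)] else NA_real_

  # True cycle durations are those of the activity window: the first cycle
  # starts at the first contraction and the last ends at the last relaxation
  # (activity after it does not exist), so the end cycles are shorter than
  # their nominal draws and the durations sum exactly to tt.
  d_true <- d
  bnd_true <- tb
  if (is.finite(a_true) && is.finite(b_true)) {
    bnd_true[1] <- a_true
    bnd_true[n_cyc + 1L] <- b_true
    d_true <- diff(bnd_true)
  }

  em_true <- amp * d * (spec$tonic_frac * 0.5 + 0.5 * spec$duty_quadriceps)
  truth_fatigue <- if (n_cyc >= 3 && is.finite(a_true)) {
    cend <- pmin(tb[-1], b_true) - a_true
    prof <- fatigue_point(em_true, cend, b_true - a_true, degree = 2)
    prof$fatigue_pct
  } else NA_real_

  trend <- if (n_cyc >= 2) fit_cycle_trend(d_true)$a_hat else NA_real_

  truth <- list(
    seed = seed, fs = fs,
    a = a_true, b = b_true, tt = b_true - a_true,
    cycle_boundaries = bnd_true, nominal_boundaries = tb,
    n_cycles = n_cyc, tc = d_true, tc_nominal = d,
    t_bar = mean(d_true), sigma = if (n_cyc >= 2) stats::sd(d_true) else NA_real_,
    a_hat = trend, drift_injected = spec$cycle_time_drift_s,
    em = em_true, energy_peak_frac = spec$energy_peak_frac,
    fatigue_pct = truth_fatigue,
    peak_times_quadriceps = peak_q, peak_times_biceps = peak_b
  )
  list(recording = rec, truth = truth)
}

#' Named simulation presets for typical rower profiles
#'
#' Four behavioral profiles used throughout the test-suite and documentation:
#' \describe{
#'   \item{athlete}{Stable rhythm (low cycle-time SD), small drift, energy
#'     still rising at the end (fatigue 0%), legs before arms every stroke.}
#'   \item{vigorous_amateur}{Fast, erratic strokes with the arms firing
#'     before the legs and an early energy peak (early fatigue).}
#'   \item{chaotic_amateur}{Very large cycle-time SD: no sustained rhythm.}
#'   \item{endurance_amateur}{Long, steady cycles with low drift: endurance
#'     but little power.}
#' }
#'
#' @return Named list of [simulation_spec] objects.
#' @export
athlete_and_amateur_presets <- function() {
  list(
    athlete = simulation_spec(
      n_cycles = 46, cycle_time_s = 1.35, cycle_time_sd_s = 0.07,
      cycle_time_drift_s = 0.005, biceps_lag_s = 0.20, energy_peak_frac = 1.0,
      idle_pre_s = 12, idle_post_s = 10, group = "athlete"),
    vigorous_amateur = simulation_spec(
      n_cycles = 40, cycle_time_s = 1.5, cycle_time_sd_s = 0.21,
      cycle_time_drift_s = 0.012, biceps_lag_s = -0.15, energy_peak_frac = 0.35,
      group = "non_athlete"),
    chaotic_amateur = simulation_spec(
      n_cycles = 40, cycle_time_s = 1.6, cycle_time_sd_s = 0.30,
      cycle_time_drift_s = 0.018, biceps_lag_s = 0.10, energy_peak_frac = 0.5,
      group = "non_athlete"),
    endurance_amateur = simulation_spec(
      n_cycles = 34, cycle_time_s = 2.2, cycle_time_sd_s = 0.08,
      cycle_time_drift_s = 0.004, biceps_lag_s = 0.20, energy_peak_frac = 0.8,
      group = "non_athlete")
  )
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth Ground-truth list from [generate_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(c(list(schema = "rowemg-truth/1"), truth), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
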