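# Per-individual metrics against closed forms and brute-force oracles.

test_that("cycle-time statistics use the sample (Nc - 1) denominator", {
  cs <- cycle_set_of(list(c(0, 1, 0), c(0, 1, 1, 0), c(0, 1, 1, 1, 0)), fs = 2)
  # durations 1, 1.5, 2
  st <- cycle_time_stats(cs)
  expect_equal(st$t_bar, 1.5)
  expect_equal(st$sigma, 0.5)

  eq <- cycle_set_of(rep(list(c(0, 1, 0)), 5), fs = 2)
  expect_equal(cycle_time_stats(eq)$sigma, 0)

  one <- cycle_set_of(list(c(0, 1, 0)), fs = 2)
  expect_error(cycle_time_stats(one), class = "rowemg_error_insufficient")
})

test_that("rhythm-drift line is exact on linear data and matches the OLS oracle", {
  flat <- fit_cycle_trend(rep(1.4, 8))
  expect_equal(flat$a_hat, 0)
  expect_equal(flat$b_hat, 1.4)

  lin <- fit_cycle_trend(0.5 * (1:10) + 1)
  expect_equal(lin$a_hat, 0.5, tolerance = 1e-12)
  expect_equal(lin$b_hat, 1, tolerance = 1e-12)

  set.seed(41)
  for (rep_i in 1:20) {
    tc <- runif(sample(5:40, 1), 1, 3)
    fit <- fit_cycle_trend(tc)
    orc <- oracle_ols(tc)
    expect_equal(fit$a_hat, unname(orc["slope"]), tolerance = 1e-10)
    expect_equal(fit$b_hat, unname(orc["intercept"]), tolerance = 1e-10)
  }
  expect_error(fit_cycle_trend(1.5), class = "rowemg_error_insufficient")
})

test_that("least-absolute-deviations trend resists a duration outlier", {
  tc <- c(rep(1.5, 20), 4.5)
  lad <- fit_cycle_trend(tc, method = "lad")
  ols <- fit_cycle_trend(tc, method = "ols")
  expect_lt(abs(lad$a_hat), abs(ols$a_hat))
  expect_equal(lad$b_hat, 1.5, tolerance = 0.01)
})

test_that("muscle energy is the trapezoidal integral of each segment", {
  # constant 1 uV over 2 s -> 2 uV.s (trapezoid exact on constants)
  expect_equal(muscle_energy(cycle_set_of(list(rep(1, 21)), fs = 10)), 2)
  expect_equal(muscle_energy(cycle_set_of(list(rep(0, 21)), fs = 10)), 0)

  set.seed(42)
  segs <- lapply(1:6, function(i) abs(rnorm(sample(20:80, 1))))
  for (i in 1:5) segs[[i + 1]][1] <- segs[[i]][length(segs[[i]])]
  cs2 <- cycle_set_of(segs, fs = 50)
  em <- muscle_energy(cs2)
  for (i in seq_along(segs)) {
    expect_equal(em[i],
                 oracle_trapz((seq_along(segs[[i]]) - 1) / 50, segs[[i]]),
                 tolerance = 1e-12)
  }
  # linearity: doubling the envelope doubles every cycle energy
  cs3 <- cycle_set_of(lapply(segs, function(s) 2 * s), fs = 50)
  expect_equal(muscle_energy(cs3), 2 * em, tolerance = 1e-12)
})

test_that("per-cycle energies add up to the whole-window integral", {
  set.seed(43)
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  y <- abs(sin(2 * pi * 0.5 * t)) + 0.05
  bounds <- exercise_bounds(1, 29, fs, 201L, 5801L)
  cs <- split_cycles(env_of(y, fs), bounds, 0.2)
  whole <- oracle_trapz(t[201:5801], y[201:5801])
  expect_equal(sum(muscle_energy(cs)), whole, tolerance = 1e-6 * whole)
})

test_that("fatigue point follows the fitted-parabola vertex, clamped to the window", {
  tt <- 100
  tc_end <- seq(2.5, tt, by = 2.5)

  # exact quadratic peaking at 0.6 tt -> fatigue 40%
  em <- 50 - (tc_end - 0.6 * tt)^2 / 200
  prof <- fatigue_point(em, tc_end, tt)
  expect_equal(prof$fatigue_pct, 40, tolerance = 0.5)
  expect_equal(prof$t_peak, 60, tolerance = 0.5)

  # strictly increasing energies: fitted maximum at/after tt -> exactly 0
  inc <- fatigue_point(1 + 0.5 * tc_end + 0.001 * tc_end^2, tc_end, tt)
  expect_identical(inc$fatigue_pct, 0)

  # strictly decreasing energies: peak clamps to the window start -> ~100%
  dec <- fatigue_point(100 - 0.8 * tc_end, tc_end, tt)
  expect_gte(dec$fatigue_pct, 95)

  expect_error(fatigue_point(c(1, 2), c(1, 2), 10, degree = 2),
               class = "rowemg_error_insufficient")
})

test_that("cycle peaks find modes with sufficient prominence", {
  fs <- 100
  t <- seq(0, 1.2, by = 1 / fs)
  unimodal <- exp(-((t - 0.5) / 0.1)^2)
  two_bump <- exp(-((t - 0.3) / 0.06)^2) + exp(-((t - 0.8) / 0.06)^2)
  flat <- rep(0, length(t))
  cs <- cycle_set_of(list(unimodal, two_bump, flat), fs = fs)
  pk <- cycle_peaks(cs)
  expect_identical(pk$n_peaks, c(1L, 2L, 0L))
  expect_equal(pk$per_cycle[[1]]$time, 0.5, tolerance = 1 / fs)
  expect_equal(pk$per_cycle[[2]]$time, c(0.3, 0.8), tolerance = 2 / fs)
  expect_true(is.na(pk$principal_time[3]))
})

test_that("activation order compares principal peaks per cycle", {
  fs <- 100
  t <- seq(0, 1.2, by = 1 / fs)
  bump <- function(mu) exp(-((t - mu) / 0.08)^2)
  quad <- cycle_set_of(list(bump(0.3), bump(0.6)), fs = fs)
  bic_ok <- cycle_set_of(list(bump(0.6), bump(0.6)), fs = fs)
  res <- phase_order(quad, bic_ok)
  expect_identical(res$violations, 0L)
  expect_true(all(res$per_cycle$order_ok))

  bic_bad <- cycle_set_of(list(bump(0.1), bump(0.3)), fs = fs)
  res2 <- phase_order(quad, bic_bad)
  expect_identical(res2$violations, 2L)

  mismatched <- cycle_set_of(list(bump(0.3)), fs = fs)
  expect_error(phase_order(quad, mismatched), class = "rowemg_error_parameter")
})

test_that("overlay normalization has unit maximum and is idempotent", {
  seg <- exp(-((seq(0, 1, length.out = 120) - 0.4) / 0.15)^2)
  same <- normalize_cycles(rep(list(3.7 * seg), 5), n_points = 80)
  expect_equal(max(same$matrix), 1)
  for (r in 1:5) expect_equal(same$matrix[r, ], same$mean)
  expect_equal(same$min, same$max)

  # resampling a linear ramp reproduces the ramp exactly
  ramp <- normalize_cycles(list(seq(0, 2, length.out = 57)), n_points = 31)
  expect_equal(ramp$matrix[1, ], seq(0, 1, length.out = 31), tolerance = 1e-9)

  # idempotence on already-normalized, already-resampled cycles
  once <- normalize_cycles(lapply(1:4, function(i) i * seg), n_points = 64)
  twice <- normalize_cycles(lapply(seq_len(4), function(r) once$matrix[r, ]),
                            n_points = 64)
  expect_equal(twice$matrix, once$matrix, tolerance = 1e-12)
})

test_that("three-way split puts remainder cycles into the fatigue third", {
  cs9 <- cycle_set_of(rep(list(c(0, 1, 0)), 9), fs = 2)
  expect_identical(three_phase_split(cs9)$sizes,
                   c(warmup = 3L, exercise = 3L, fatigue = 3L))
  cs10 <- cycle_set_of(rep(list(c(0, 1, 0)), 10), fs = 2)
  sp <- three_phase_split(cs10)
  expect_identical(sp$sizes, c(warmup = 3L, exercise = 3L, fatigue = 4L))
  expect_identical(sp$fatigue, 7:10)
  cs2 <- cycle_set_of(rep(list(c(0, 1, 0)), 2), fs = 2)
  expect_error(three_phase_split(cs2), class = "rowemg_error_insufficient")
})

test_that("recommendation flags fire on the documented profiles", {
  ref <- athlete_reference()
  expect_length(recommend_training(ref$tt, ref$sigma, ref$t_bar, ref$a_hat, 0), 0)
  expect_identical(
    recommend_training(ref$tt, 3 * ref$sigma, ref$t_bar, ref$a_hat, 0),
    "rhythm_work")
  expect_true("endurance_path" %in%
                recommend_training(60, ref$sigma, 1.5, 0.012, fatigue_pct = 65))
  expect_true("strength_path" %in%
                recommend_training(110, ref$sigma, 2.2, 0.004, fatigue_pct = 10))
})
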