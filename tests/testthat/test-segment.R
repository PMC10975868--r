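# Exercise-window detection, trough-prominence cycle splitting, and the
# duration-conservation identity.

test_that("bounds land on the 10% crossings of a triangular envelope", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  y <- pmax(0, 1 - abs(t - 15) / 5)   # 0 at 10 s, peak at 15 s, 0 at 20 s
  b <- detect_bounds(env_of(y, fs))
  expect_equal(b$a, 10.5, tolerance = 2 / fs)
  expect_equal(b$b, 19.5, tolerance = 2 / fs)
  expect_equal(b$tt, 9.0, tolerance = 4 / fs)
  expect_identical(b$tt, b$b - b$a)
})

test_that("a side with no crossing is bounded by the signal edge", {
  fs <- 100
  y <- seq(0, 1, length.out = 2000)   # strictly increasing ramp
  b <- detect_bounds(env_of(y, fs))
  expect_equal(b$a, which(y >= 0.1)[1] / fs - 1 / fs, tolerance = 2 / fs)
  expect_identical(b$b_index, 2000L)
})

test_that("degenerate envelopes raise a no-exercise error", {
  expect_error(detect_bounds(env_of(rep(0, 100))),
               class = "rowemg_error_noexercise")
  # activity that never drops below threshold: no distinguishable window
  expect_error(detect_bounds(env_of(rep(5, 100) + 0.01 * sin(1:100))),
               class = "rowemg_error_noexercise")
})

test_that("bounds are invariant to amplitude scaling", {
  fs <- 100
  t <- seq(0, 40, by = 1 / fs)
  y <- pmax(0, sin(2 * pi * (t - 12) / 16)) * (t > 12 & t < 20)
  for (k in c(1, 0.01, 250)) {
    b <- detect_bounds(env_of(k * y, fs))
    expect_identical(b$a_index, detect_bounds(env_of(y, fs))$a_index)
    expect_identical(b$b_index, detect_bounds(env_of(y, fs))$b_index)
  }
})

test_that("a sinusoidal envelope splits into one segment per period", {
  fs <- 200
  for (K in c(3, 8)) {
    # trough-to-trough window holding exactly K periods: K - 1 interior minima
    t <- seq(0, K + 4, by = 1 / fs)
    y <- 1 + sin(2 * pi * t)
    env <- env_of(y, fs)
    a_idx <- which.min(abs(t - 0.75))
    b_idx <- which.min(abs(t - (0.75 + K)))
    bounds <- exercise_bounds(t[a_idx], t[b_idx], fs, a_idx, b_idx)
    cs <- split_cycles(env, bounds)
    expect_equal(cs$n_cycles, K)
    expect_equal(cs$tc, rep(1, K), tolerance = 2 / fs)
  }
})

test_that("a monotone ramp inside bounds yields a single cycle", {
  fs <- 100
  y <- seq(0.1, 1, length.out = 1000)
  cs <- split_cycles(env_of(y, fs), exercise_bounds(1, 8, fs, 101L, 801L))
  expect_identical(cs$n_cycles, 1L)
})

test_that("durations always sum to the training time (conservation)", {
  fs <- 250
  set.seed(31)
  for (rep_i in 1:20) {
    # random smooth multi-bump envelope
    t <- seq(0, 30, by = 1 / fs)
    y <- abs(rowSums(vapply(1:6, function(k)
      runif(1, 0.3, 1) * sin(2 * pi * runif(1, 0.2, 0.6) * t + runif(1, 0, 6)),
      numeric(length(t))))) + 0.01
    a_idx <- sample(100:500, 1)
    b_idx <- sample(5000:7000, 1)
    bounds <- exercise_bounds(t[a_idx], t[b_idx], fs, a_idx, b_idx)
    cs <- split_cycles(env_of(y, fs), bounds, min_prominence_frac = 0.1)
    expect_lt(abs(sum(cs$tc) - bounds$tt), 1 / fs)
    expect_identical(cs$n_cycles, length(cs$segments))
  }
})

test_that("raising the prominence threshold never increases the cycle count", {
  fs <- 250
  set.seed(32)
  t <- seq(0, 40, by = 1 / fs)
  y <- abs(sin(2 * pi * 0.5 * t) + 0.5 * sin(2 * pi * 1.3 * t) + 0.2) + 0.01
  bounds <- exercise_bounds(2, 38, fs, 501L, 9501L)
  fracs <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8)
  ncs <- vapply(fracs, function(f)
    split_cycles(env_of(y, fs), bounds, f)$n_cycles, integer(1))
  expect_true(all(diff(ncs) <= 0))
})

test_that("splitting is invariant to amplitude scaling", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  y <- 1.2 + sin(2 * pi * 0.7 * t)
  bounds <- exercise_bounds(1, 19, fs, 201L, 3801L)
  base <- split_cycles(env_of(y, fs), bounds)
  for (k in c(0.001, 40)) {
    expect_identical(split_cycles(env_of(k * y, fs), bounds)$boundary_idx,
                     base$boundary_idx)
  }
})

test_that("trough prominences match the brute-force definition", {
  set.seed(33)
  for (rep_i in 1:25) {
    z <- cumsum(rnorm(60))
    z <- (z - min(z)) / diff(range(z))
    tr <- rowemg:::trough_prominences(z)
    for (r in seq_len(nrow(tr))) {
      expect_equal(tr$prominence[r], oracle_trough_prominence(z, tr$idx[r]),
                   tolerance = 1e-12)
    }
  }
})

test_that("plateau troughs are marked once, at their midpoint", {
  y <- c(5, 4, 3, 1, 1, 1, 3, 4, 5)
  tr <- rowemg:::trough_prominences(y / max(y))
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$idx, 5L)
})

test_that("suspicious cycle durations are flagged by the multiple rule", {
  cs <- cycle_set_of(list(c(0, 1, 0), c(0, 1, 0), c(0, 1, 1, 1, 0), c(0, 1, 0)),
                     fs = 2)
  # durations 1, 1, 2 (= 2x median), 1 at fs = 2 Hz: the long one is flagged
  expect_identical(validate_cycles(cs), 3L)

  all_equal <- cycle_set_of(rep(list(c(0, 1, 0)), 4), fs = 2)
  expect_length(validate_cycles(all_equal), 0)

  # 1.0 s cycle against t_bar = 1.67: half-multiple is 0.83, 1.0 is >15% off
  mixed <- cycle_set_of(list(c(0, 1, 1, 1, 0), c(0, 1, 0), c(0, 1, 1, 1, 0)),
                        fs = 2)
  expect_length(validate_cycles(mixed, t_bar = 5 / 3), 0)
})
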