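# Independent brute-force oracles and small fixture builders. Every oracle
# here is written from the defining formula, not from the package code paths
# it checks.

# Trailing moving average by direct summation with truncated prefix.
oracle_moving_average <- function(x, Nw) {
  vapply(seq_along(x), function(n) {
    lo <- max(1, n - Nw + 1)
    mean(x[lo:n])
  }, numeric(1))
}

# Sample standard deviation from its definition (n - 1 denominator).
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Closed-form OLS slope/intercept over (i, y), i = 1..n.
oracle_ols <- function(y) {
  i <- seq_along(y)
  sl <- sum((i - mean(i)) * (y - mean(y))) / sum((i - mean(i))^2)
  c(slope = sl, intercept = mean(y) - sl * mean(i))
}

# Trapezoidal integral by explicit panel summation.
oracle_trapz <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Topographic prominence of the trough at index `i0` of `z`, by definition:
# walk outward until a strictly lower value (on the inverted signal: higher
# trough) appears or the edge is hit; the base on each side is the highest
# value passed (lowest on the inverted signal).
oracle_trough_prominence <- function(z, i0) {
  h <- -z[i0]
  base_side <- function(idx_seq) {
    b <- Inf
    for (j in idx_seq) {
      if (-z[j] > h) break
      b <- min(b, -z[j])
    }
    b
  }
  left <- if (i0 > 1) base_side(seq(i0 - 1, 1)) else Inf
  right <- if (i0 < length(z)) base_side(seq(i0 + 1, length(z))) else Inf
  h - max(left, right)
}

# Envelope fixture: a bare emg_envelope around a numeric vector.
env_of <- function(samples, fs = 100) {
  emg_envelope(samples, fs, source_role = "quadriceps")
}

# Small, fast simulation spec for tests that only need a plausible signal.
quick_spec <- function(...) {
  args <- utils::modifyList(
    list(n_cycles = 12, cycle_time_s = 1.5, idle_pre_s = 8, idle_post_s = 8,
         n_spikes_pre = 1, n_spikes_post = 1),
    list(...)
  )
  do.call(simulation_spec, args)
}

# Build a cycle_set directly from a list of segments (shared boundaries are
# implied by segment lengths), for metric tests that need exact inputs.
cycle_set_of <- function(segments, fs = 100) {
  lens <- vapply(segments, length, integer(1))
  boundary_idx <- cumsum(c(1L, lens - 1L))
  env <- emg_envelope(
    unlist(lapply(seq_along(segments), function(i) {
      s <- segments[[i]]
      if (i == length(segments)) s else s[-length(s)]
    })),
    fs, source_role = "quadriceps"
  )
  rowemg:::new_cycle_set(env, boundary_idx)
}
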