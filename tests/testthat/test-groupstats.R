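# Pooled-variance t-test from summary statistics and the group-comparison
# stage, including reproduction of the reference-cohort table bundled under
# extdata (8 + 5 rowers, five performance variables).

test_that("pooled t from summary statistics reproduces the cohort table", {
  sm <- utils::read.csv(system.file("extdata", "rowing_cohort_summary.csv",
                                    package = "rowemg"))
  expected_t <- c(tt = 3.3983, Nc = 0.1333, sigma = 4.1275, t_bar = 3.6388,
                  a_hat = 2.6318)
  expected_p <- c(tt = 0.0059, Nc = 0.8964, sigma = 0.0017, t_bar = 0.0039,
                  a_hat = 0.0233)
  # SD rounding in the printed inputs leaves ~1e-3 residuals on two rows
  tol <- c(tt = 1e-3, Nc = 1e-3, sigma = 2e-3, t_bar = 2e-3, a_hat = 1e-3)
  for (i in seq_len(nrow(sm))) {
    r <- sm[i, ]
    res <- pooled_t_from_summary(r$mean1, r$sd1, r$n1, r$mean2, r$sd2, r$n2)
    v <- r$variable
    expect_lt(abs(res$t - expected_t[v]), tol[v])
    expect_lt(abs(res$p - expected_p[v]), 1e-3)
    expect_equal(res$df, r$n1 + r$n2 - 2)
  }
})

test_that("the t statistic is antisymmetric and p is monotone in |t|", {
  set.seed(51)
  for (rep_i in 1:20) {
    m <- rnorm(2, 10, 5); s <- runif(2, 0.5, 3); n <- sample(3:12, 2, TRUE)
    a <- pooled_t_from_summary(m[1], s[1], n[1], m[2], s[2], n[2])
    b <- pooled_t_from_summary(m[2], s[2], n[2], m[1], s[1], n[1])
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  df <- 11
  ts <- seq(0.1, 5, by = 0.3)
  ps <- vapply(ts, function(t0) 2 * stats::pt(-t0, df), numeric(1))
  got <- vapply(ts, function(t0)
    pooled_t_from_summary(t0, 1, 8, 0, 1, 5)$p, numeric(1))
  expect_true(all(diff(got) < 0))
  expect_equal(got[1] > got[5], ps[1] > ps[5])
})

test_that("degenerate summaries are handled explicitly", {
  eq <- pooled_t_from_summary(5, 2, 8, 5, 2, 5)
  expect_identical(eq$t, 0)
  expect_identical(eq$p, 1)
  zero_var <- pooled_t_from_summary(5, 0, 8, 5, 0, 5)
  expect_identical(zero_var$t, 0)
  expect_error(pooled_t_from_summary(5, 0, 8, 6, 0, 5),
               class = "rowemg_error_parameter")
  expect_error(pooled_t_from_summary(5, 1, 1, 6, 1, 5),
               class = "rowemg_error_parameter")
})

fake_report <- function(id, group, tt, nc, sigma, t_bar, a_hat) {
  structure(list(subject_id = id, group = group, tt_s = tt, n_cycles = nc,
                 sigma_s = sigma, t_bar_s = t_bar, a_hat_s_per_cycle = a_hat),
            class = "metrics_report")
}

draw_reports <- function(n, group, shift = 0) {
  lapply(seq_len(n), function(i)
    fake_report(sprintf("%s%02d", group, i), group,
                tt = rnorm(1, 100 + shift, 15), nc = rnorm(1, 60, 10),
                sigma = rnorm(1, 0.1, 0.02), t_bar = rnorm(1, 1.6, 0.2),
                a_hat = rnorm(1, 0.005, 0.002)))
}

test_that("compare_groups builds the five-variable table with group stats", {
  set.seed(52)
  reports <- c(draw_reports(8, "athlete"), draw_reports(5, "non_athlete", 30))
  cmp <- compare_groups(reports)
  expect_identical(nrow(cmp$table), 5L)
  expect_setequal(cmp$table$variable, c("tt", "Nc", "sigma", "t_bar", "a_hat"))
  expect_identical(cmp$n, c(8L, 5L))
  expect_true(all(cmp$table$df == 11))
  # the injected tt shift of 2 pooled SDs should dominate the table
  row_tt <- cmp$table[cmp$table$variable == "tt", ]
  expect_lt(row_tt$p, 0.05)

  expect_error(compare_groups(draw_reports(5, "athlete")),
               class = "rowemg_error_insufficient")
  expect_error(compare_groups(c(draw_reports(4, "a"), draw_reports(1, "b"))),
               class = "rowemg_error_insufficient")
})

test_that("comparison round-trips through JSON and TSV writers", {
  set.seed(53)
  reports <- c(draw_reports(4, "athlete"), draw_reports(4, "non_athlete"))
  cmp <- compare_groups(reports)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(cmp, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$table$t, cmp$table$t)
  tsv <- utils::read.delim(tp)
  expect_identical(nrow(tsv), 5L)
})

test_that("type-I error of the comparison stage is calibrated at alpha = 0.05", {
  set.seed(54)
  n_rep <- 1000
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    x <- rnorm(8); y <- rnorm(5)   # identical distributions
    res <- pooled_t_from_summary(mean(x), sd(x), 8, mean(y), sd(y), 5)
    if (res$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.03)
  expect_lte(rejections / n_rep, 0.07)
})

test_that("the comparison detects a 2-pooled-SD group difference with power > 0.8", {
  set.seed(55)
  n_rep <- 500
  hits <- 0L
  for (r in seq_len(n_rep)) {
    x <- rnorm(8, 2, 1); y <- rnorm(5, 0, 1)   # separation of 2 pooled SDs
    res <- pooled_t_from_summary(mean(x), sd(x), 8, mean(y), sd(y), 5)
    if (res$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.8)
})
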