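# Two-group comparison of per-individual metrics with the pooled-variance
# unpaired (Student) t-test, computable either from collections of metrics
# reports or directly from printed summary statistics (means, SDs, n).

#' Pooled-variance unpaired t-test from summary statistics
#'
#' Student's two-sample t-test assuming equal variances:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))`, with a two-tailed p value on
#' `n1 + n2 - 2` degrees of freedom. Computable from printed group summaries
#' alone, which is how published group tables are reproduced. Set
#' `welch = TRUE` for the unequal-variance (Welch) form instead.
#'
#' @param m1,s1,n1 Mean, sample SD and size of group 1.
#' @param m2,s2,n2 Mean, sample SD and size of group 2.
#' @param welch Use the Welch statistic and Welch-Satterthwaite df.
#' @return List of class `t_test_result`: `t`, `df`, `p`, `method`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop_rowemg("parameter", "both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop_rowemg("parameter", "SDs must be nonnegative")
  if (s1 == 0 && s2 == 0) {
    if (m1 != m2)
      stop_rowemg("parameter", "zero pooled variance with unequal means: t is infinite")
    return(structure(list(t = 0, df = n1 + n2 - 2, p = 1, method = "pooled"),
                     class = "t_test_result"))
  }
  if (welch) {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "welch"
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  }
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), method = method),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4f, df = %.2f, p = %.4f (%s)\n",
              x$t, x$df, x$p, x$method))
  invisible(x)
}

comparison_variables <- c(tt = "tt_s", Nc = "n_cycles", sigma = "sigma_s",
                          t_bar = "t_bar_s", a_hat = "a_hat_s_per_cycle")

#' Compare two groups of metrics reports
#'
#' For each performance variable (tt, Nc, sigma, t_bar, a_hat) computes the
#' per-group mean and sample SD and the unpaired t-test between the two
#' groups. No multiple-testing correction is applied by default;
#' `bonferroni = TRUE` adds an adjusted p column.
#'
#' @param reports List of [metrics_report] objects; group membership is taken
#'   from each report's `group` field unless `labels` overrides it.
#' @param labels Optional data frame with columns `subject_id` and `group`.
#' @param welch Use the Welch test instead of the pooled form.
#' @param bonferroni Add Bonferroni-adjusted p values.
#' @return Object of class `group_comparison`: a data frame `table` with one
#'   row per variable, plus the group names and sizes.
#' @export
compare_groups <- function(reports, labels = NULL, welch = FALSE, bonferroni = FALSE) {
  if (length(reports) < 4L)
    stop_rowemg("insufficient", "need at least 2 reports per group")
  groups <- vapply(reports, function(r) r$group, character(1))
  if (!is.null(labels)) {
    ids <- vapply(reports, function(r) r$subject_id, character(1))
    m <- match(ids, labels$subject_id)
    if (any(is.na(m))) stop_rowemg("config", "labels missing for some subjects")
    groups <- as.character(labels$group[m])
  }
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop_rowemg("insufficient", "exactly 2 groups required (got %d)", length(lev))
  g1 <- which(groups == lev[1])
  g2 <- which(groups == lev[2])
  if (length(g1) < 2L || length(g2) < 2L)
    stop_rowemg("insufficient", "each group needs at least 2 reports")

  rows <- lapply(names(comparison_variables), function(vn) {
    field <- comparison_variables[[vn]]
    v <- vapply(reports, function(r) as.numeric(r[[field]]), numeric(1))
    tst <- pooled_t_from_summary(mean(v[g1]), stats::sd(v[g1]), length(g1),
                                 mean(v[g2]), stats::sd(v[g2]), length(g2),
                                 welch = welch)
    data.frame(variable = vn,
               mean1 = mean(v[g1]), sd1 = stats::sd(v[g1]), n1 = length(g1),
               mean2 = mean(v[g2]), sd2 = stats::sd(v[g2]), n2 = length(g2),
               t = tst$t, df = tst$df, p = tst$p)
  })
  tab <- do.call(rbind, rows)
  if (bonferroni) tab$p_adj <- pmin(1, tab$p * nrow(tab))
  structure(list(table = tab, groups = lev,
                 n = c(length(g1), length(g2)),
                 method = if (welch) "welch" else "pooled"),
            class = "group_comparison")
}

#' Group comparison from printed summary statistics
#'
#' Reproduces a published comparison table directly from per-variable group
#' means, SDs and sizes, without access to the underlying recordings.
#'
#' @param summary_df Data frame with columns `variable`, `mean1`, `sd1`,
#'   `mean2`, `sd2` and either per-row `n1`/`n2` columns or the `n1`/`n2`
#'   arguments.
#' @param n1,n2 Group sizes applied to every row when the data frame does not
#'   carry them.
#' @param welch Use the Welch test instead of the pooled form.
#' @return A `group_comparison`.
#' @export
compare_from_summary <- function(summary_df, n1 = NULL, n2 = NULL, welch = FALSE) {
  need <- c("variable", "mean1", "sd1", "mean2", "sd2")
  if (!all(need %in% names(summary_df)))
    stop_rowemg("config", "summary needs columns: %s", paste(need, collapse = ", "))
  if (is.null(summary_df$n1)) summary_df$n1 <- n1
  if (is.null(summary_df$n2)) summary_df$n2 <- n2
  if (is.null(summary_df$n1) || is.null(summary_df$n2))
    stop_rowemg("config", "group sizes n1 and n2 are required")
  rows <- lapply(seq_len(nrow(summary_df)), function(i) {
    r <- summary_df[i, ]
    tst <- pooled_t_from_summary(r$mean1, r$sd1, r$n1, r$mean2, r$sd2, r$n2,
                                 welch = welch)
    cbind(r[need], n1 = r$n1, n2 = r$n2, t = tst$t, df = tst$df, p = tst$p)
  })
  tab <- do.call(rbind, rows)
  names(tab) <- c("variable", "mean1", "sd1", "mean2", "sd2", "n1", "n2", "t", "df", "p")
  structure(list(table = tab, groups = c("group1", "group2"),
                 n = c(summary_df$n1[1], summary_df$n2[1]),
                 method = if (welch) "welch" else "pooled"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (n = %d, %d; %s t-test)\n",
              x$groups[1], x$groups[2], x$n[1], x$n[2], x$method))
  print(format(x$table, digits = 5), row.names = FALSE)
  invisible(x)
}

#' Write a group comparison as JSON and TSV
#'
#' @param cmp A `group_comparison`.
#' @param json_path,tsv_path Output paths (`NULL` skips that format).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(cmp, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(cmp, "group_comparison"))
  if (!is.null(json_path))
    jsonlite::write_json(list(schema = "rowemg-comparison/1", groups = cmp$groups,
                              n = cmp$n, method = cmp$method, table = cmp$table),
                         json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(tsv_path))
    utils::write.table(cmp$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
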