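# Recording and report I/O: the data model shared by every pipeline stage.
#
# Recordings are plain delimited text (comma default, tab accepted) with a
# `# fs_hz: <value>` header comment followed by a column-name row. Raw
# amplitudes are carried in microvolts as metadata, never converted.

#' Construct an sEMG recording
#'
#' A recording bundles the sampling rate, one or more equal-length channels of
#' raw amplitude samples (in \eqn{\mu}V), and subject metadata. Channels are
#' named by their physiological role; the pipeline expects `"quadriceps"` and
#' (optionally) `"biceps"`, plus an ignored `"reference"` channel if present.
#'
#' Sampling below 1000 Hz triggers a warning (not an error): surface EMG
#' carries most of its power below 400 Hz, so the sampling theorem asks for at
#' least 1000 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param channels Named list of equal-length finite numeric vectors
#'   (amplitudes in \eqn{\mu}V). Sample `n` (0-based) occurs at time `n/fs` s.
#' @param subject_id Opaque subject label.
#' @param group One of `"athlete"`, `"non_athlete"`, `"unknown"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(fs, channels, subject_id = "anonymous",
                          group = c("unknown", "athlete", "non_athlete")) {
  group <- match.arg(group)
  if (!is_number(fs) || fs <= 0) stop_rowemg("parameter", "fs must be a positive number")
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop_rowemg("parameter", "channels must be a named list")
  lens <- vapply(channels, length, integer(1))
  if (any(lens < 2L)) stop_rowemg("parameter", "every channel needs at least 2 samples")
  if (length(unique(lens)) != 1L)
    stop_rowemg("format", "channel lengths differ: %s", paste(lens, collapse = ", "))
  for (nm in names(channels)) {
    if (!is.numeric(channels[[nm]]) || !all(is.finite(channels[[nm]])))
      stop_rowemg("parameter", "channel '%s' contains non-finite values", nm)
  }
  if (fs < 1000)
    warning(sprintf("fs = %g Hz is below the 1000 Hz recommended for sEMG", fs))
  structure(
    list(fs = fs, channels = channels, subject_id = subject_id, group = group),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf(
    "<emg_recording> subject=%s group=%s fs=%g Hz, %d samples (%.1f s), channels: %s\n",
    x$subject_id, x$group, x$fs, n, n / x$fs, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Read an sEMG recording from delimited text
#'
#' The file must start with comment lines of the form `# key: value`
#' (minimally `# fs_hz`), followed by a column-name row and numeric data rows.
#' Comma- and tab-separated files are both accepted; the separator is sniffed
#' from the column-name row.
#'
#' @param path Path to the recording file.
#' @param channel_map Named character vector mapping channel roles to file
#'   column names, e.g. `c(quadriceps = "quad", biceps = "bic")`. The
#'   `quadriceps` role is required.
#' @return An [emg_recording].
#' @export
read_recording <- function(path,
                           channel_map = c(quadriceps = "quadriceps", biceps = "biceps")) {
  if (!file.exists(path)) stop_rowemg("io", "no such file: %s", path)
  head_lines <- readLines(path, n = 64L, warn = FALSE)
  if (length(head_lines) == 0L) stop_rowemg("format", "empty recording file: %s", path)
  comments <- grep("^\\s*#", head_lines, value = TRUE)
  meta <- parse_header_comments(comments)
  if (is.null(meta$fs_hz))
    stop_rowemg("format", "missing '# fs_hz:' header in %s", path)
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (!is_number(fs) || fs <= 0)
    stop_rowemg("format", "invalid fs_hz header value: %s", meta$fs_hz)

  name_row <- head_lines[!grepl("^\\s*#", head_lines) & nzchar(trimws(head_lines))][1]
  if (is.na(name_row)) stop_rowemg("format", "no column-name row in %s", path)
  sep <- if (grepl("\t", name_row)) "\t" else ","

  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L) stop_rowemg("format", "no data rows in %s", path)

  if (is.null(names(channel_map)) || !("quadriceps" %in% names(channel_map)))
    stop_rowemg("config", "channel_map must map at least the 'quadriceps' role")
  channels <- list()
  for (role in names(channel_map)) {
    col <- channel_map[[role]]
    if (!(col %in% names(df))) {
      if (role == "quadriceps")
        stop_rowemg("config", "required role 'quadriceps' maps to missing column '%s'", col)
      next  # optional role absent from this file
    }
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0)
      stop_rowemg("parse", "non-numeric value '%s' in column '%s', data row %d",
                  raw[bad[1]], col, bad[1])
    channels[[role]] <- val
  }
  emg_recording(fs, channels,
                subject_id = meta$subject_id %||% "anonymous",
                group = meta$group %||% "unknown")
}

parse_header_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Write an sEMG recording to delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_recording(write_recording(x))` round-trips bit-for-bit.
#'
#' @param rec An [emg_recording].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "emg_recording"))
  n <- length(rec$channels[[1]])
  t <- (seq_len(n) - 1) / rec$fs
  cols <- c(list(t = t), rec$channels)
  header <- c(
    sprintf("# fs_hz: %.17g", rec$fs),
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# group: %s", rec$group),
    paste(names(cols), collapse = sep)
  )
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)), sep = sep))
  con <- tryCatch(file(path, "w"), error = function(e) stop_rowemg("io", "cannot open %s", path))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

# -- metrics report -----------------------------------------------------------

#' Assemble a per-individual metrics report
#'
#' Collects every per-individual parameter the pipeline computes into one
#' validated structure. Invariants enforced: the per-cycle durations must sum
#' to the training time within one sample period, the fatigue percentage must
#' lie in \[0, 100\], and at least one cycle must be present.
#'
#' @param subject_id,group Subject metadata.
#' @param tt_s Training time in seconds.
#' @param n_cycles Number of stroke cycles.
#' @param tc_s Per-cycle durations in seconds.
#' @param t_bar_s,sigma_s Mean and sample SD of `tc_s` (SD may be `NA` when
#'   only one cycle exists, but such a report cannot be serialized).
#' @param a_hat_s_per_cycle,b_hat_s Rhythm-drift regression slope/intercept.
#' @param em Named list of per-cycle energy vectors (\eqn{\mu}V s), one per
#'   muscle.
#' @param fatigue_pct Headline (quadriceps) fatigue percentage in \[0, 100\].
#' @param fatigue Named list of per-muscle fatigue percentages.
#' @param peaks Named list of per-muscle peak summaries (counts and times).
#' @param phase_order Activation-order result (or `NULL` if biceps missing).
#' @param phases Warm-up/exercise/fatigue three-way split summary (or `NULL`).
#' @param recommendations Character vector of advisory training flags.
#' @param fs Sampling rate in Hz (used for the conservation tolerance).
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(subject_id, group, tt_s, n_cycles, tc_s, t_bar_s,
                           sigma_s, a_hat_s_per_cycle, b_hat_s, em, fatigue_pct,
                           fatigue = NULL, peaks = NULL, phase_order = NULL,
                           phases = NULL, recommendations = character(), fs) {
  if (n_cycles < 1L) stop_rowemg("invalid", "a report needs at least one cycle")
  if (abs(sum(tc_s) - tt_s) > 1 / fs + 1e-9)
    stop_rowemg("invalid", "cycle durations sum to %.6f s but tt is %.6f s", sum(tc_s), tt_s)
  if (!is.na(fatigue_pct) && (fatigue_pct < 0 || fatigue_pct > 100))
    stop_rowemg("invalid", "fatigue_pct %.3f outside [0, 100]", fatigue_pct)
  structure(list(
    schema = "rowemg-report/1",
    subject_id = subject_id, group = group, fs = fs,
    tt_s = tt_s, n_cycles = as.integer(n_cycles), tc_s = tc_s,
    t_bar_s = t_bar_s, sigma_s = sigma_s,
    a_hat_s_per_cycle = a_hat_s_per_cycle, b_hat_s = b_hat_s,
    em = em, fatigue_pct = fatigue_pct, fatigue = fatigue,
    peaks = peaks, phase_order = phase_order, phases = phases,
    recommendations = recommendations,
    units = list(time = "s", amplitude = "uV", energy = "uV.s",
                 a_hat = "s/cycle", fatigue = "percent")
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  tt = %.2f s over Nc = %d cycles; t_bar = %.3f s, sigma = %.3f s\n",
              x$tt_s, x$n_cycles, x$t_bar_s, x$sigma_s))
  cat(sprintf("  drift a_hat = %+.4f s/cycle, fatigue = %.1f%%\n",
              x$a_hat_s_per_cycle, x$fatigue_pct))
  if (!is.null(x$phase_order))
    cat(sprintf("  phase-order violations: %d / %d cycles\n",
                x$phase_order$violations, x$n_cycles))
  if (length(x$recommendations))
    cat("  recommendations:", paste(x$recommendations, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report as schema-versioned JSON
#'
#' All numeric fields are serialized at full precision; a report whose sigma
#' is `NaN`/`NA` (single-cycle case) is refused so the caller handles it
#' upstream.
#'
#' @param report A [metrics_report].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  if (is.null(report$sigma_s) || !is.finite(report$sigma_s))
    stop_rowemg("invalid", "refusing to serialize a report with non-finite sigma")
  out <- tryCatch(
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null"),
    error = function(e) stop_rowemg("io", "cannot write report to %s: %s", path, conditionMessage(e))
  )
  invisible(path)
}

#' Read a metrics report written by [write_report()]
#'
#' @param path Path to a report JSON file.
#' @return A [metrics_report].
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_rowemg("io", "no such file: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "rowemg-report/1"))
    stop_rowemg("format", "%s is not a rowemg-report/1 document", path)
  x$em <- lapply(x$em, as.numeric)
  structure(x, class = "metrics_report")
}
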