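#' Uniformly sampled waveform
#'
#' Container for a single-channel waveform: samples (arbitrary PPG units),
#' sampling frequency, record identifier and optional manually labelled
#' artifact spans.
#'
#' @param samples Non-empty numeric vector.
#' @param fs Sampling frequency in Hz, positive.
#' @param record_id Identifier string, default `"record"`.
#' @param artifact_spans Optional data.frame with `start_s` and `end_s`
#'   columns, spans inside the record duration.
#' @return Object of class `"sampled_signal"`.
#' @export
sampled_signal <- function(samples, fs, record_id = "record",
                           artifact_spans = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty",
                                  call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  if (!is.null(artifact_spans)) {
    stopifnot(all(c("start_s", "end_s") %in% names(artifact_spans)))
    dur <- length(samples) / fs
    if (any(artifact_spans$start_s < 0 | artifact_spans$end_s > dur |
            artifact_spans$start_s > artifact_spans$end_s)) {
      stop("artifact spans must lie within the record duration",
           call. = FALSE)
    }
  }
  structure(list(samples = samples, fs = fs, record_id = record_id,
                 artifact_spans = artifact_spans),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("sampled_signal '%s': %d samples @ %g Hz (%.1f s)%s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$artifact_spans)) "" else
                sprintf(", %d artifact spans", nrow(x$artifact_spans))))
  invisible(x)
}

#' Read a waveform from CSV
#'
#' Accepts either a two-column file (`time_s`, value) with a uniformly
#' spaced time column, or a single value column plus an explicit
#' `fs_override`.  Uniformity is validated: the maximum deviation of the
#' time increments from their median must stay below 1\% of the sample
#' period.  The record id is the file name without extension.
#'
#' @param path CSV path (header expected).
#' @param fs_override Sampling frequency in Hz, required when the file has
#'   no time column; when given together with a time column it takes
#'   precedence after the uniformity check.
#' @return A [sampled_signal()].
#' @export
read_signal_csv <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("format error: empty file", call. = FALSE)
  record_id <- tools::file_path_sans_ext(basename(path))
  time_col <- intersect(c("time_s", "time"), names(df))
  if (length(time_col) > 0L) {
    tm <- df[[time_col[1L]]]
    val_col <- setdiff(names(df), time_col[1L])[1L]
    if (is.na(val_col)) stop("format error: no value column", call. = FALSE)
    dt <- diff(tm)
    period <- stats::median(dt)
    if (period <= 0 || any(abs(dt - period) > 0.01 * period)) {
      if (is.null(fs_override)) {
        stop("format error: time column not uniformly spaced ",
             "(max jitter above 1% of the sample period)", call. = FALSE)
      }
      stop("format error: time column not uniformly spaced", call. = FALSE)
    }
    fs <- if (is.null(fs_override)) 1 / period else fs_override
    sampled_signal(df[[val_col]], fs, record_id = record_id)
  } else {
    if (is.null(fs_override)) {
      stop("format error: no time column and no 'fs_override'",
           call. = FALSE)
    }
    sampled_signal(df[[1L]], fs_override, record_id = record_id)
  }
}

#' Write a waveform to CSV
#'
#' Two columns, `time_s` and `ppg`.
#'
#' @param signal A [sampled_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  t <- (seq_along(signal$samples) - 1) / signal$fs
  utils::write.csv(data.frame(time_s = t, ppg = signal$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write rate estimates to CSV
#'
#' Columns `window_center_s`, `hr_bpm`, `rr_brpm`, `hr_hz`, `rr_hz`,
#' `flags`; one row per window.  Values round-trip losslessly at 6
#' significant digits through [read_estimates()].
#'
#' @param estimates data.frame from [estimate_rates()].
#' @param path Output path.
#' @param header_lines Optional character vector written verbatim above the
#'   CSV header, each line starting with `#` (used by the CLI to echo the
#'   effective configuration).
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, header_lines = NULL) {
  cols <- c("window_center_s", "hr_bpm", "rr_brpm", "hr_hz", "rr_hz",
            "flags")
  stopifnot(all(cols %in% names(estimates)))
  df <- as.data.frame(estimates)[, cols]
  for (col in setdiff(cols, "flags")) {
    df[[col]] <- signif(df[[col]], 10)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    bad <- !startsWith(header_lines, "#")
    header_lines[bad] <- paste0("# ", header_lines[bad])
    writeLines(header_lines, con)
  }
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read rate estimates from CSV
#'
#' @param path A file written by [write_estimates()] (leading `#` comment
#'   lines are skipped).
#' @return data.frame with the estimate columns; empty rate fields become
#'   `NA`.
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Export a spectrum as a two-column table
#'
#' @param spectrum An `ar_spectrum`.
#' @param path Output CSV path (`freq_hz`, `density`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ar_spectrum"))
  utils::write.csv(data.frame(freq_hz = spectrum$freqs,
                              density = spectrum$density),
                   path, row.names = FALSE)
  invisible(path)
}
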