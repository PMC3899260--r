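#' Pair windowed estimates with reference rates
#'
#' Aligns an instantaneous reference rate series to estimation windows: all
#' reference values with timestamps inside
#' `[center - window_s/2, center + window_s/2]` are reduced to their
#' median.  Windows whose reference slice is empty are dropped (their
#' count is reported via the `"n_dropped"` attribute).
#'
#' @param estimates data.frame with `window_center_s` and an estimate
#'   column (`rate` or e.g. `rr_brpm` named via `estimate_col`).
#' @param reference data.frame with `time_s` and `rate` (instantaneous
#'   reference, same units as the estimates).
#' @param window_s Window length in seconds used for the estimates.
#' @param estimate_col Name of the estimate column, default `"rate"`.
#' @return data.frame (`window_center_s`, `estimated`, `reference`), the
#'   paired-rates table consumed by [rms_error()] and [bland_altman()].
#' @export
pair_rates <- function(estimates, reference, window_s,
                       estimate_col = "rate") {
  stopifnot(estimate_col %in% names(estimates),
            all(c("time_s", "rate") %in% names(reference)))
  half <- window_s / 2
  rows <- lapply(seq_len(nrow(estimates)), function(i) {
    ctr <- estimates$window_center_s[i]
    est <- estimates[[estimate_col]][i]
    sel <- reference$time_s >= ctr - half & reference$time_s <= ctr + half
    if (!any(sel) || is.na(est)) return(NULL)
    data.frame(window_center_s = ctr, estimated = est,
               reference = stats::median(reference$rate[sel]))
  })
  kept <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(window_center_s = numeric(0), estimated = numeric(0),
               reference = numeric(0))
  attr(out, "n_dropped") <- nrow(estimates) - nrow(out)
  out
}

#' Unnormalized RMS error of paired rates
#'
#' \deqn{\mathrm{RMS} = \sqrt{\frac{1}{n}\sum_{i=1}^n
#'   (\mathrm{ref}_i - \mathrm{est}_i)^2}.}
#'
#' @param pairs data.frame with `estimated` and `reference` columns (as
#'   from [pair_rates()]), at least one row.
#' @return Non-negative scalar in the rate units of the inputs.
#' @export
rms_error <- function(pairs) {
  stopifnot(all(c("estimated", "reference") %in% names(pairs)))
  if (nrow(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  sqrt(mean((pairs$reference - pairs$estimated)^2))
}

#' Cohort summary of per-subject RMS errors
#'
#' Median and first/third quartiles of a vector of per-subject RMS errors,
#' the cohort-level accuracy summary for a non-normal error distribution.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param per_subject_rms Numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
cohort_summary <- function(per_subject_rms) {
  if (length(per_subject_rms) < 1L) stop("empty input", call. = FALSE)
  q <- stats::quantile(per_subject_rms, c(0.5, 0.25, 0.75), names = FALSE,
                       type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Bland-Altman agreement summary
#'
#' Differences are oriented `estimated - reference`; the bias is their
#' mean and the limits of agreement are `bias -/+ 1.96 * sd` with the
#' sample (n-1) standard deviation.
#'
#' @param pairs data.frame with `estimated` and `reference`.
#' @return Object of class `"agreement_summary"`: list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff` and `n`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(all(c("estimated", "reference") %in% names(pairs)))
  d <- pairs$estimated - pairs$reference
  if (length(d) < 1L) stop("need at least one pair", call. = FALSE)
  bias <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else 0
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 sd_diff = s,
                 n = length(d)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Kernel scale-factor sweep
#'
#' Runs the estimation pipeline at several kernel scale factors over a
#' cohort of records with reference rates and tabulates the median
#' per-record respiratory RMS error per factor — the experiment shape used
#' to calibrate the 10x-Silverman default.
#'
#' @param signals List of [sampled_signal()] records.
#' @param references List (same length) of data.frames with `time_s` and
#'   `rate` (reference RR in breaths/min).
#' @param scale_factors Numeric vector of kernel scale factors, default
#'   `c(1, 5, 10, 20)`.
#' @param config Base [pipeline_config()]; its `scale_factor` is
#'   overridden per sweep point.
#' @return data.frame with columns `scale_factor` and `rr_rms_median`.
#' @export
sweep_kernel_scale <- function(signals, references,
                               scale_factors = c(1, 5, 10, 20),
                               config = pipeline_config()) {
  stopifnot(length(signals) == length(references))
  rows <- lapply(scale_factors, function(sc) {
    cfg <- config
    cfg$scale_factor <- sc
    rms <- vapply(seq_along(signals), function(i) {
      est <- estimate_rates(signals[[i]], cfg)
      pairs <- pair_rates(est, references[[i]], cfg$window_s,
                          estimate_col = "rr_brpm")
      if (nrow(pairs) == 0L) return(NA_real_)
      rms_error(pairs)
    }, numeric(1))
    data.frame(scale_factor = sc,
               rr_rms_median = stats::median(rms, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
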