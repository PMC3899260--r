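#' Pipeline configuration
#'
#' All tunable parameters of the sliding-window rate estimator.
#'
#' @param window_s Window length in seconds, 60 or 120 (default 120).
#'   Other lengths only with `allow_any_window = TRUE`.
#' @param overlap_fraction Window overlap in (0, 1), default 0.5.
#' @param hr_band Cardiac search band in Hz, default `c(0.5, 3)`
#'   (30-180 beats/min).
#' @param rr_band Respiratory search band in Hz, default `c(0.14, 1)`
#'   (8.4-60 breaths/min).
#' @param elevated_rr_hz Elevated-RR threshold gating the harmonic
#'   exclusion, default 0.75 Hz (45 breaths/min).
#' @param lowpass_offset Cardiac-removal cutoff is `f_hr - lowpass_offset`
#'   Hz, default 0.1.
#' @param lowpass_order Butterworth order of the zero-phase cardiac-removal
#'   filter (applied forward-backward), default 4.
#' @param method `"csd"` (default) or `"psd"`.
#' @param scale_factor Kernel width multiplier on the Silverman bandwidth,
#'   default 10.
#' @param hr_rate Target sampling rate (Hz) of the cardiac stage; the
#'   record is decimated by `round(fs / hr_rate)` with zero-phase
#'   anti-alias filtering.  Default 10.
#' @param rr_decim Additional integer decimation factor applied to the
#'   cardiac-filtered window before the respiratory spectrum, default 3
#'   (respiratory stage at `hr_rate / rr_decim` Hz).  Slow respiratory
#'   poles are heavily oversampled at the cardiac rate; the extra
#'   decimation keeps their angles well conditioned for the Yule-Walker
#'   fit.
#' @param harmonic_tol Frequency tolerance (Hz) of the harmonic-exclusion
#'   rule, default 0.1 (the one tolerance the cardiac-removal cutoff also
#'   uses).
#' @param p_min,p_max AR order bounds for MDL selection, defaults 5 and 15.
#' @param lag_margin Extra correntropy lags computed beyond `p_max`
#'   (unused by the fit), default 0.
#' @param n_freqs Spectral grid size, default 4096.
#' @param allow_any_window Escape hatch for non-standard window lengths.
#' @return Object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(window_s = 120,
                            overlap_fraction = 0.5,
                            hr_band = c(0.5, 3),
                            rr_band = c(0.14, 1),
                            elevated_rr_hz = 0.75,
                            lowpass_offset = 0.1,
                            lowpass_order = 4L,
                            method = c("csd", "psd"),
                            scale_factor = 10,
                            hr_rate = 10,
                            rr_decim = 3L,
                            harmonic_tol = 0.1,
                            p_min = 5L,
                            p_max = 15L,
                            lag_margin = 0L,
                            n_freqs = 4096L,
                            allow_any_window = FALSE) {
  method <- match.arg(method)
  if (!allow_any_window && !window_s %in% c(60, 120)) {
    stop("'window_s' must be 60 or 120 (set allow_any_window = TRUE to ",
         "override)", call. = FALSE)
  }
  if (window_s <= 0) stop("'window_s' must be positive", call. = FALSE)
  if (overlap_fraction <= 0 || overlap_fraction >= 1) {
    stop("'overlap_fraction' must be in (0, 1)", call. = FALSE)
  }
  stopifnot(length(hr_band) == 2L, hr_band[1] < hr_band[2],
            length(rr_band) == 2L, rr_band[1] < rr_band[2])
  if (rr_band[2] > hr_band[2]) {
    stop("'rr_band' upper edge must not exceed 'hr_band' upper edge",
         call. = FALSE)
  }
  if (p_min < 1L || p_max < p_min) stop("invalid AR order bounds",
                                        call. = FALSE)
  if (scale_factor <= 0) stop("'scale_factor' must be positive",
                              call. = FALSE)
  if (hr_rate <= 2 * hr_band[2]) {
    stop("'hr_rate' must exceed twice the cardiac band top", call. = FALSE)
  }
  if (rr_decim < 1L || rr_decim != round(rr_decim)) {
    stop("'rr_decim' must be a positive integer", call. = FALSE)
  }
  if (hr_rate / rr_decim <= 2 * rr_band[2]) {
    stop("respiratory stage rate must exceed twice the respiratory band ",
         "top", call. = FALSE)
  }
  structure(list(window_s = window_s,
                 overlap_fraction = overlap_fraction,
                 hr_band = hr_band, rr_band = rr_band,
                 elevated_rr_hz = elevated_rr_hz,
                 lowpass_offset = lowpass_offset,
                 lowpass_order = as.integer(lowpass_order),
                 method = method,
                 scale_factor = scale_factor,
                 hr_rate = hr_rate,
                 rr_decim = as.integer(rr_decim),
                 harmonic_tol = harmonic_tol,
                 p_min = as.integer(p_min), p_max = as.integer(p_max),
                 lag_margin = as.integer(lag_margin),
                 n_freqs = as.integer(n_freqs),
                 allow_any_window = allow_any_window),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "pipeline_config: %s, %gs windows (%.0f%% overlap), HR %.2f-%.2f Hz, RR %.2f-%.2f Hz\n",
    x$method, x$window_s, 100 * x$overlap_fraction,
    x$hr_band[1], x$hr_band[2], x$rr_band[1], x$rr_band[2]))
  invisible(x)
}

#' Decimate a signal to (approximately) a target rate
#'
#' Integer-factor decimation with zero-phase Chebyshev anti-alias
#' filtering (via [signal::decimate()]).  The factor is
#' `round(fs / target_rate)`; a factor of 1 returns the input unchanged.
#'
#' @param x Numeric samples.
#' @param fs Input sampling rate, Hz.
#' @param target_rate Desired rate, Hz.
#' @return List with `samples` and achieved `fs`.
#' @keywords internal
decimate_to <- function(x, fs, target_rate) {
  q <- max(1L, round(fs / target_rate))
  if (q == 1L) return(list(samples = x, fs = fs))
  if (stats::sd(x) == 0) {
    # a constant record decimates to itself; the anti-alias filter would
    # only add edge transients
    return(list(samples = x[seq.int(1L, length(x), by = q)], fs = fs / q))
  }
  list(samples = as.numeric(signal::decimate(x, q)), fs = fs / q)
}

#' Segment a record into overlapping windows
#'
#' Sliding windows of `window_s` seconds with `overlap_fraction` overlap;
#' window starts fall on multiples of `window_s * (1 - overlap_fraction)`
#' and a trailing partial window is discarded.
#'
#' @param signal A [sampled_signal()].
#' @param config A [pipeline_config()].
#' @return List of windows, each a list with `samples`, `fs`, `start_s`,
#'   `center_s` and `index`.
#' @export
segment_windows <- function(signal, config = pipeline_config()) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal$fs
  n <- length(signal$samples)
  wlen <- round(config$window_s * fs)
  if (n < wlen) {
    stop("record too short: ", round(n / fs, 2), " s but window is ",
         config$window_s, " s", call. = FALSE)
  }
  step <- round(config$window_s * (1 - config$overlap_fraction) * fs)
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    list(samples = signal$samples[s0:(s0 + wlen - 1L)],
         fs = fs,
         start_s = (s0 - 1L) / fs,
         center_s = (s0 - 1L) / fs + config$window_s / 2,
         index = i)
  })
}

#' Local spectral maxima within a band
#'
#' Interior local maxima of the density restricted to `[band[1], band[2]]`,
#' sorted by decreasing density (ties toward lower frequency).
#'
#' @param spectrum An `ar_spectrum`.
#' @param band Length-2 numeric, Hz.
#' @return data.frame with columns `freq` and `density` (possibly 0 rows).
#' @keywords internal
band_local_maxima <- function(spectrum, band) {
  f <- spectrum$freqs
  d <- spectrum$density
  n <- length(d)
  i <- 2:(n - 1L)
  lm <- i[d[i] > d[i - 1L] & d[i] >= d[i + 1L]]
  lm <- lm[f[lm] >= band[1] & f[lm] <= band[2]]
  ord <- order(-d[lm], f[lm])
  data.frame(freq = f[lm][ord], density = d[lm][ord])
}

#' Frequency of the dominant peak in a band
#'
#' Returns the frequency of the highest-density interior local maximum
#' inside the band; if the band contains no interior local maximum, falls
#' back to the band-restricted argmax.  Ties break toward the lowest
#' frequency.
#'
#' @param spectrum An `ar_spectrum`.
#' @param band Length-2 numeric band in Hz, inside the spectrum's grid.
#' @return Peak frequency in Hz.
#' @export
detect_band_peak <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "ar_spectrum"), length(band) == 2L)
  f <- spectrum$freqs
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("no spectral grid points inside the band",
                      call. = FALSE)
  cand <- band_local_maxima(spectrum, band)
  if (nrow(cand) > 0L) return(cand$freq[1L])
  fb <- f[sel]
  fb[which.max(spectrum$density[sel])]
}

#' Remove the cardiac component by zero-phase low-pass filtering
#'
#' Butterworth low-pass at `f_hr - lowpass_offset` Hz applied
#' forward-backward ([signal::filtfilt()]), so the output has zero group
#' delay and the same length as the input.
#'
#' @param x Numeric window samples.
#' @param fs Sampling rate, Hz.
#' @param f_hr Detected cardiac frequency, Hz.
#' @param config A [pipeline_config()].
#' @return Filtered samples, same length as `x`.
#' @export
remove_cardiac <- function(x, fs, f_hr, config = pipeline_config()) {
  cutoff <- f_hr - config$lowpass_offset
  if (cutoff <= config$rr_band[1]) {
    stop("filter infeasible: cutoff ", round(cutoff, 3),
         " Hz at or below the respiratory band edge", call. = FALSE)
  }
  if (cutoff >= fs / 2) {
    stop("filter infeasible: cutoff at or above Nyquist", call. = FALSE)
  }
  bt <- signal::butter(config$lowpass_order, cutoff / (fs / 2), "low")
  as.numeric(signal::filtfilt(bt, x))
}

#' Select the respiratory peak among band candidates
#'
#' Takes the respiratory-band local maxima (strongest first) and applies,
#' in order: a cardiac-residual guard discarding candidates within
#' `harmonic_tol` of `f_hr` (the cardiac line just filtered can survive
#' the low-pass when `f_hr` is inside the respiratory band); then, only if
#' the remaining top candidate exceeds the elevated-RR threshold, the
#' harmonic exclusions — candidates within `harmonic_tol` of `f_hr / 2`,
#' and candidates within `harmonic_tol` of `f_hr - g` for an already
#' retained stronger candidate `g` (the lower AM sideband image).  If every
#' candidate is excluded the original top candidate is returned with the
#' `harmonic_excluded` flag.
#'
#' @param candidates data.frame with `freq` and `density`, sorted by
#'   decreasing density (as from [band_local_maxima()]); non-empty.
#' @param f_hr Detected cardiac frequency, Hz.
#' @param config A [pipeline_config()].
#' @return List with `freq` (selected Hz) and `harmonic_excluded`
#'   (logical: fell back to an excluded candidate).
#' @export
exclude_hr_harmonics <- function(candidates, f_hr,
                                 config = pipeline_config()) {
  if (nrow(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  tol <- config$harmonic_tol
  top0 <- candidates$freq[1L]
  cand <- candidates[abs(candidates$freq - f_hr) > tol, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(freq = top0, harmonic_excluded = TRUE))
  }
  if (cand$freq[1L] <= config$elevated_rr_hz) {
    return(list(freq = cand$freq[1L], harmonic_excluded = FALSE))
  }
  cand <- cand[abs(cand$freq - f_hr / 2) > tol, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$freq[seq_len(i - 1L)][keep[seq_len(i - 1L)]]
    keep[i] <- !any(abs(cand$freq[i] - (f_hr - g)) <= tol)
  }
  if (any(keep)) {
    list(freq = cand$freq[keep][1L], harmonic_excluded = FALSE)
  } else {
    list(freq = top0, harmonic_excluded = TRUE)
  }
}

#' Estimate heart and respiratory rate over sliding windows
#'
#' Per window: spectrum of the (decimated) window; cardiac peak in
#' `hr_band`; zero-phase low-pass 0.1 Hz below the cardiac peak; further
#' decimation; second spectrum; respiratory candidates in `rr_band`
#' filtered through [exclude_hr_harmonics()].  A failing window yields a
#' flagged row with `NA` rates — the run never aborts on a single window.
#'
#' @param signal A [sampled_signal()].
#' @param config A [pipeline_config()].
#' @return data.frame (class `"rate_estimates"`) with one row per window:
#'   `window_center_s`, `hr_hz`, `hr_bpm`, `rr_hz`, `rr_brpm`, `flags`
#'   (comma-separated among `harmonic_excluded`, `regularized`,
#'   `artifact_window`, `degenerate`, `filter_infeasible`).
#' @export
estimate_rates <- function(signal, config = pipeline_config()) {
  stopifnot(inherits(signal, "sampled_signal"))
  dec <- decimate_to(signal$samples, signal$fs, config$hr_rate)
  dsig <- sampled_signal(dec$samples, dec$fs, record_id = signal$record_id)
  windows <- segment_windows(dsig, config)
  spec_fun <- if (config$method == "csd") csd else psd

  rows <- lapply(windows, function(w) {
    flags <- character(0)
    if (!is.null(signal$artifact_spans) &&
        nrow(signal$artifact_spans) > 0L) {
      w_end <- w$start_s + config$window_s
      if (any(signal$artifact_spans$start_s < w_end &
              signal$artifact_spans$end_s > w$start_s)) {
        flags <- c(flags, "artifact_window")
      }
    }
    hr_hz <- rr_hz <- NA_real_
    tryCatch({
      # near-constant guard: anti-alias filtering of a flat record leaves
      # only rounding-level wiggle, which must not masquerade as signal
      if (stats::sd(w$samples) <=
          1e-10 * max(abs(w$samples), 1)) {
        stop("degenerate signal: constant window")
      }
      sp1 <- spec_fun(w$samples, w$fs, config)
      if (isTRUE(attr(sp1, "regularized"))) {
        flags <- c(flags, "regularized")
      }
      hr_hz <- detect_band_peak(sp1, config$hr_band)
      xf <- remove_cardiac(w$samples, w$fs, hr_hz, config)
      dec2 <- decimate_to(xf, w$fs, w$fs / config$rr_decim)
      sp2 <- spec_fun(dec2$samples, dec2$fs, config)
      if (isTRUE(attr(sp2, "regularized")) &&
          !"regularized" %in% flags) {
        flags <- c(flags, "regularized")
      }
      rr_top <- min(config$rr_band[2], dec2$fs / 2)
      cand <- band_local_maxima(sp2, c(config$rr_band[1], rr_top))
      if (nrow(cand) == 0L) {
        rr_hz <- detect_band_peak(sp2, c(config$rr_band[1], rr_top))
      } else {
        sel <- exclude_hr_harmonics(cand, hr_hz, config)
        rr_hz <- sel$freq
        if (sel$harmonic_excluded) flags <- c(flags, "harmonic_excluded")
      }
    }, error = function(e) {
      msg <- conditionMessage(e)
      flag <- if (grepl("degenerate", msg)) "degenerate"
              else if (grepl("filter infeasible", msg)) "filter_infeasible"
              else "degenerate"
      flags <<- c(flags, flag)
    })
    data.frame(window_center_s = w$center_s,
               hr_hz = hr_hz, hr_bpm = 60 * hr_hz,
               rr_hz = rr_hz, rr_brpm = 60 * rr_hz,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_estimates", "data.frame")
  attr(out, "config") <- config
  attr(out, "record_id") <- signal$record_id
  out
}
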