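#' Simulation specification for a synthetic PPG signal
#'
#' Parameters of the amplitude-modulated cardiac carrier with a
#' respiration-synchronized baseline shift,
#' \deqn{x(t) = \left(1 + m \cos(2\pi f_r t)\right) \cos(2\pi f_c t)
#'   + b \cos(2\pi f_r t).}
#' Respiration leaves two imprints on a PPG: the baseline shift (the `b`
#' term) and amplitude modulation of the cardiac pulse (the `m` term);
#' respiratory sinus arrhythmia (frequency modulation of the carrier) is
#' deliberately not modelled.
#'
#' @param f_c Cardiac frequency, Hz.
#' @param f_r Respiratory frequency, Hz; must be below `f_c`.
#' @param m Modulation index in `[0, 1)`, default 0.3.
#' @param b Baseline-shift amplitude (signal units), default 0.3.
#' @param fs Sampling rate in Hz, default 100 (must exceed `2 * f_c`).
#' @param duration_s Signal duration in seconds, default 120.
#' @param n_outliers Impulsive outliers to inject (see
#'   [inject_outliers()]), default 100.
#' @param seed RNG seed for outlier placement, default 1.
#' @return Object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(f_c = 1, f_r = 0.2, m = 0.3, b = 0.3,
                            fs = 100, duration_s = 120,
                            n_outliers = 100L, seed = 1L) {
  if (f_r >= f_c) stop("'f_r' must be below 'f_c'", call. = FALSE)
  if (fs <= 2 * f_c) stop("'fs' must exceed 2 * f_c", call. = FALSE)
  if (m < 0 || m >= 1) stop("'m' must be in [0, 1)", call. = FALSE)
  if (duration_s <= 0) stop("'duration_s' must be positive", call. = FALSE)
  if (n_outliers < 0 || n_outliers > fs * duration_s) {
    stop("'n_outliers' must be in [0, fs * duration_s]", call. = FALSE)
  }
  structure(list(f_c = f_c, f_r = f_r, m = m, b = b, fs = fs,
                 duration_s = duration_s,
                 n_outliers = as.integer(n_outliers),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "simulation_spec: f_c=%g Hz, f_r=%g Hz, m=%g, b=%g, %g s @ %g Hz, %d outliers (seed %d)\n",
    x$f_c, x$f_r, x$m, x$b, x$duration_s, x$fs, x$n_outliers, x$seed))
  invisible(x)
}

#' Simulate a clean synthetic PPG signal
#'
#' Deterministic evaluation of the AM-plus-baseline model of
#' [simulation_spec()] on `round(fs * duration_s)` samples (no outliers;
#' see [inject_outliers()]).  The ground-truth frequencies are attached as
#' the `"truth"` attribute.
#'
#' @param spec A [simulation_spec()].
#' @return A [sampled_signal()] with attribute `truth = list(f_c, f_r)`.
#' @export
simulate_ppg <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  x <- (1 + spec$m * cos(2 * pi * spec$f_r * t)) *
    cos(2 * pi * spec$f_c * t) +
    spec$b * cos(2 * pi * spec$f_r * t)
  out <- sampled_signal(x, spec$fs, record_id = "simulated")
  attr(out, "truth") <- list(f_c = spec$f_c, f_r = spec$f_r)
  out
}

#' Inject impulsive outliers into a signal
#'
#' Replaces `n_outliers` distinct, uniformly chosen sample positions with
#' values drawn uniformly from
#' `[mean(x) - 5 sd(x), mean(x) + 5 sd(x)]` of the *original* signal —
#' the impulsive-noise model used to probe the robustness of the
#' correntropy spectrum.  Deterministic given `seed`; the RNG state of the
#' session is left untouched.
#'
#' @param signal A [sampled_signal()] (or numeric vector with `fs`
#'   irrelevant).
#' @param n_outliers Number of samples to replace, default 100.
#' @param seed RNG seed.
#' @return Signal of the same type with attribute `outlier_idx` giving the
#'   replaced positions.
#' @export
inject_outliers <- function(signal, n_outliers = 100L, seed = 1L) {
  x <- if (inherits(signal, "sampled_signal")) signal$samples else signal
  n <- length(x)
  if (n_outliers > n) {
    stop("'n_outliers' exceeds the signal length", call. = FALSE)
  }
  if (n_outliers > 0L) {
    mu <- mean(x)
    s <- stats::sd(x)
    rng <- local({
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      idx <- sample.int(n, n_outliers)
      vals <- stats::runif(n_outliers, mu - 5 * s, mu + 5 * s)
      list(idx = idx, vals = vals)
    })
    x[rng$idx] <- rng$vals
    idx_out <- sort(rng$idx)
  } else {
    idx_out <- integer(0)
  }
  if (inherits(signal, "sampled_signal")) {
    out <- signal
    out$samples <- x
  } else {
    out <- x
  }
  attr(out, "outlier_idx") <- idx_out
  out
}

#' Simulate a PPG record including outliers
#'
#' Convenience wrapper: [simulate_ppg()] then [inject_outliers()] with the
#' spec's `n_outliers` and `seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A [sampled_signal()] with `truth` and `outlier_idx` attributes.
#' @export
simulate_ppg_noisy <- function(spec = simulation_spec()) {
  clean <- simulate_ppg(spec)
  out <- inject_outliers(clean, spec$n_outliers, spec$seed)
  attr(out, "truth") <- attr(clean, "truth")
  out
}
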