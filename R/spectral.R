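#' Levinson-Durbin recursion over all orders
#'
#' Solves the Yule-Walker Toeplitz systems for every order `1..p_max` in a
#' single recursion.  Internal workhorse behind [levinson_yule_walker()],
#' [select_order_mdl()] and the spectrum constructors.
#'
#' @param seq Lag-indexed sequence, `seq[1]` the zero lag; needs at least
#'   `p_max + 1` entries with `seq[1] > 0`.
#' @param p_max Highest order to solve for.
#' @return List with `phi` (list of forward-prediction coefficient vectors
#'   per order, starting at order 0), `eps` (prediction-error powers per
#'   order) and `valid` (logical per order; FALSE from the first order at
#'   which the prediction error is non-positive, i.e. the Toeplitz matrix
#'   stopped being positive definite).
#' @keywords internal
levinson_recursion <- function(seq, p_max) {
  if (length(seq) < p_max + 1L) {
    stop("'seq' needs at least p_max + 1 lags", call. = FALSE)
  }
  if (!is.finite(seq[1L]) || seq[1L] <= 0) {
    stop("numerical degeneracy: zero-lag value must be positive",
         call. = FALSE)
  }
  eps <- numeric(p_max + 1L)
  eps[1L] <- seq[1L]
  phi <- vector("list", p_max + 1L)
  phi[[1L]] <- numeric(0)
  valid <- rep(TRUE, p_max + 1L)
  for (k in seq_len(p_max)) {
    if (!valid[k] || eps[k] <= 0) {
      valid[k:(p_max + 1L)] <- FALSE
      break
    }
    pk <- phi[[k]]
    num <- seq[k + 1L] - if (k > 1L) sum(pk * seq[k:2L]) else 0
    kap <- num / eps[k]
    newphi <- c(pk, kap)
    if (k > 1L) newphi[1:(k - 1L)] <- pk - kap * rev(pk)
    phi[[k + 1L]] <- newphi
    eps[k + 1L] <- eps[k] * (1 - kap^2)
    if (!is.finite(eps[k + 1L]) || eps[k + 1L] <= 0) {
      valid[(k + 1L):(p_max + 1L)] <- FALSE
    }
  }
  list(phi = phi, eps = eps, valid = valid)
}

#' Fit an AR model to a lag sequence by Yule-Walker
#'
#' Solves the order-`p` Yule-Walker equations for the Toeplitz system built
#' from `seq` via the Levinson-Durbin recursion.  Coefficients are returned
#' in the spectral-denominator sign convention, i.e. the AR polynomial is
#' \eqn{A(z) = 1 + \sum_k a_k z^{-k}}, so they equal minus the
#' forward-prediction coefficients and agree (to numerical precision) with
#' `-solve(toeplitz(seq[1:p]), seq[2:(p+1)])`.
#'
#' @param seq Lag-indexed sequence (autocorrelation or centered
#'   correntropy), zero lag first.
#' @param p Model order.
#' @param source Either `"csd"` or `"psd"`; recorded on the model.
#' @return Object of class `"ar_model"`: list with `order`, `coefficients`
#'   (`a_1..a_p`), `innovation_variance` (final Levinson prediction-error
#'   power), `source` and `stable` (all characteristic roots inside the unit
#'   circle; logged, not enforced).
#' @export
levinson_yule_walker <- function(seq, p, source = c("csd", "psd")) {
  source <- match.arg(source)
  lv <- levinson_recursion(seq, p)
  if (!lv$valid[p + 1L]) {
    stop("numerical degeneracy: lag sequence is not positive definite ",
         "through order ", p, call. = FALSE)
  }
  a <- -lv$phi[[p + 1L]]
  new_ar_model(a, lv$eps[p + 1L], source)
}

new_ar_model <- function(a, innovation_variance, source) {
  p <- length(a)
  stable <- if (p == 0L) TRUE else {
    roots <- polyroot(c(rev(a), 1))  # z^p + a_1 z^(p-1) + ... + a_p
    all(Mod(roots) < 1 + 1e-10)
  }
  structure(list(order = p,
                 coefficients = a,
                 innovation_variance = innovation_variance,
                 source = source,
                 stable = stable),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("ar_model (%s): order %d, innovation variance %.6g, %s\n",
              x$source, x$order, x$innovation_variance,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Minimum-description-length AR order selection
#'
#' Selects the AR order on `p_min..p_max` minimizing Rissanen's criterion
#' \deqn{\mathrm{MDL}(p) = N \ln \varepsilon_p + p \ln N,}
#' with \eqn{\varepsilon_p} the Levinson prediction-error power at order
#' `p` and `N` the number of signal samples behind the lag estimates.
#' Ties break toward the smaller order.
#'
#' @param seq Lag-indexed sequence with at least `p_max + 1` entries.
#' @param n_samples Sample count of the segment the lags were estimated
#'   from.
#' @param p_min,p_max Order bounds, defaults 5 and 15.
#' @return Integer order in `[p_min, p_max]`.
#' @export
select_order_mdl <- function(seq, n_samples, p_min = 5L, p_max = 15L) {
  if (n_samples <= p_max) stop("'n_samples' must exceed p_max", call. = FALSE)
  lv <- levinson_recursion(seq, p_max)
  orders <- p_min:p_max
  mdl <- vapply(orders, function(p) {
    if (lv$valid[p + 1L] && lv$eps[p + 1L] > 0) {
      n_samples * log(lv$eps[p + 1L]) + p * log(n_samples)
    } else Inf
  }, numeric(1))
  if (all(!is.finite(mdl))) {
    stop("numerical degeneracy: no valid order in [p_min, p_max]",
         call. = FALSE)
  }
  orders[which.min(mdl)]
}

#' Evaluate an AR spectral density on a frequency grid
#'
#' \deqn{S(f) = \frac{\sigma^2 T_s}
#'   {\left|1 + \sum_{k=1}^p a_k e^{-i 2\pi f k T_s}\right|^2}}
#' on a uniform grid of `n_freqs` points spanning `[0, 1/(2 T_s)]`.
#' An order-0 model yields the flat spectrum \eqn{\sigma^2 T_s}.
#'
#' @param model An [`ar_model`][levinson_yule_walker].
#' @param T_s Sampling period in seconds.
#' @param n_freqs Grid size, at least 256 (default 4096).
#' @return Object of class `"ar_spectrum"`: list with `freqs` (Hz, strictly
#'   increasing from 0 to Nyquist), `density` (non-negative), `model` and
#'   `T_s`.
#' @export
ar_spectrum <- function(model, T_s, n_freqs = 4096L) {
  stopifnot(inherits(model, "ar_model"), T_s > 0)
  if (n_freqs < 256L) stop("'n_freqs' must be at least 256", call. = FALSE)
  freqs <- seq(0, 1 / (2 * T_s), length.out = n_freqs)
  a <- model$coefficients
  if (length(a) == 0L) {
    density <- rep(model$innovation_variance * T_s, n_freqs)
  } else {
    E <- exp(-2i * pi * outer(freqs * T_s, seq_along(a)))
    A <- 1 + as.vector(E %*% a)
    density <- model$innovation_variance * T_s / Mod(A)^2
  }
  structure(list(freqs = freqs, density = density, model = model, T_s = T_s),
            class = "ar_spectrum")
}

#' @export
print.ar_spectrum <- function(x, ...) {
  cat(sprintf(
    "ar_spectrum (%s): %d points, 0..%.4g Hz, AR order %d\n",
    x$model$source, length(x$freqs), max(x$freqs), x$model$order))
  invisible(x)
}

#' Fit an AR model to a lag sequence with MDL order selection and
#' regularization
#'
#' Shared back end of [csd()] and [psd()]: pick the order by MDL, fit by
#' Levinson.  Centered correntropy is not guaranteed positive definite (and
#' for nearly deterministic low-passed windows its Toeplitz matrix is close
#' to rank deficient), so when the recursion fails inside the order range a
#' relative ridge is added to the zero lag, escalating tenfold from `1e-8`
#' toward validity through `p_max` but capped at `1e-2`; MDL then selects
#' among the orders the (possibly regularized) recursion supports, and
#' only a sequence with no valid order at all is an error.
#'
#' @return List: `model` (class `ar_model`), `regularized` (logical),
#'   `delta` (ridge actually applied, 0 if none).
#' @keywords internal
fit_ar_sequence <- function(seq, n_samples, source,
                            p_min = 5L, p_max = 15L) {
  orders <- p_min:p_max
  delta_used <- 0
  lv <- levinson_recursion(seq, p_max)
  delta <- 1e-8
  while (!all(lv$valid[orders + 1L]) && delta <= 1e-2) {
    seq_r <- seq
    seq_r[1L] <- seq[1L] * (1 + delta)
    lv <- levinson_recursion(seq_r, p_max)
    delta_used <- delta
    delta <- delta * 10
  }
  if (!any(lv$valid[orders + 1L])) {
    stop("degenerate signal: lag sequence not positive definite even ",
         "after regularization", call. = FALSE)
  }
  mdl <- vapply(orders, function(p) {
    if (lv$valid[p + 1L] && lv$eps[p + 1L] > 0) {
      n_samples * log(lv$eps[p + 1L]) + p * log(n_samples)
    } else Inf
  }, numeric(1))
  p <- orders[which.min(mdl)]
  model <- new_ar_model(-lv$phi[[p + 1L]], lv$eps[p + 1L], source)
  list(model = model, regularized = delta_used > 0, delta = delta_used)
}

resolve_segment <- function(segment, fs) {
  if (inherits(segment, "sampled_signal")) {
    list(x = segment$samples, fs = segment$fs)
  } else {
    if (is.null(fs)) stop("'fs' is required for a bare numeric segment",
                          call. = FALSE)
    list(x = as.numeric(segment), fs = fs)
  }
}

#' Correntropy spectral density of a signal segment
#'
#' The CSD: centered correntropy of the segment (kernel width
#' `scale_factor` x Silverman, recomputed from this segment), AR model by
#' Yule-Walker with MDL order selection on `[p_min, p_max]`, spectrum by
#' [ar_spectrum()].  The AR parameterization of the Fourier transform of
#' the centered correntropy exposes an amplitude-modulation frequency at
#' its true position rather than as carrier sidebands, and the Gaussian
#' kernel bounds the influence of impulsive outliers.
#'
#' @param segment A [sampled_signal()] or bare numeric vector.
#' @param fs Sampling frequency in Hz (required for bare numeric input).
#' @param config A [pipeline_config()]; spectral fields used:
#'   `scale_factor`, `p_min`, `p_max`, `lag_margin`, `n_freqs`.
#' @return An `ar_spectrum` whose model carries `source = "csd"` and an
#'   attribute `regularized` flagging zero-lag ridge regularization.
#' @export
csd <- function(segment, fs = NULL, config = pipeline_config()) {
  seg <- resolve_segment(segment, fs)
  x <- seg$x
  if (length(x) < 16L * config$p_max) {
    stop("segment too short: need at least 16 x p_max samples",
         call. = FALSE)
  }
  kern <- kernel_config(x, scale_factor = config$scale_factor)
  max_lag <- config$p_max + config$lag_margin
  cseq <- centered_correntropy(x, max_lag, kern)
  fit <- fit_ar_sequence(cseq$values, length(x), "csd",
                         config$p_min, config$p_max)
  sp <- ar_spectrum(fit$model, 1 / seg$fs, config$n_freqs)
  attr(sp, "regularized") <- fit$regularized
  attr(sp, "kernel") <- kern
  sp
}

#' Power spectral density of a signal segment (AR baseline)
#'
#' Conventional second-order counterpart of [csd()] on identical AR
#' machinery: the lag sequence is the biased sample autocorrelation of the
#' mean-removed segment, then Yule-Walker with the same MDL order range.
#'
#' @inheritParams csd
#' @return An `ar_spectrum` with `source = "psd"`.
#' @export
psd <- function(segment, fs = NULL, config = pipeline_config()) {
  seg <- resolve_segment(segment, fs)
  x <- seg$x - mean(seg$x)
  if (length(x) < 16L * config$p_max) {
    stop("segment too short: need at least 16 x p_max samples",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate signal: constant segment", call. = FALSE)
  }
  max_lag <- config$p_max + config$lag_margin
  r <- as.vector(stats::acf(x, lag.max = max_lag, type = "covariance",
                            plot = FALSE, demean = FALSE)$acf)
  fit <- fit_ar_sequence(r, length(x), "psd", config$p_min, config$p_max)
  sp <- ar_spectrum(fit$model, 1 / seg$fs, config$n_freqs)
  attr(sp, "regularized") <- fit$regularized
  sp
}
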