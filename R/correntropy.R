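#' Gaussian kernel
#'
#' Density-normalized Gaussian kernel used throughout the correntropy
#' machinery,
#' \deqn{\kappa_\sigma(u) = \frac{1}{\sqrt{2\pi}\,\sigma}
#'   \exp\!\left(-\frac{u^2}{2\sigma^2}\right).}
#' The normalization cancels in all peak-location decisions; it is kept so
#' that correntropy values are on the familiar kernel-density scale.
#'
#' @param u Numeric vector of differences, in signal units.
#' @param sigma Kernel bandwidth (positive, signal units).
#' @return Strictly positive numeric vector, maximal at `u = 0` where it
#'   equals `1/(sqrt(2*pi)*sigma)`.
#' @examples
#' gaussian_kernel(0, 1)            # 1/sqrt(2*pi)
#' gaussian_kernel(1, 1) / gaussian_kernel(0, 1)  # exp(-1/2)
#' @export
gaussian_kernel <- function(u, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

#' Silverman's rule-of-thumb bandwidth
#'
#' Robust Silverman bandwidth
#' \deqn{\sigma_s = 0.9 \min(\mathrm{sd}(x), \mathrm{IQR}(x)/1.34)\,
#'   N^{-1/5},}
#' the reference bandwidth from which the correntropy kernel width is scaled.
#' Scale-equivariant: `silverman_bandwidth(a * x) == a *
#' silverman_bandwidth(x)` for `a > 0`.
#'
#' @param x Numeric vector, at least 2 non-constant values.
#' @return Positive bandwidth in the units of `x`.
#' @export
silverman_bandwidth <- function(x) {
  if (length(x) < 2L) stop("'x' must have at least 2 samples", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: constant input has no Silverman bandwidth",
         call. = FALSE)
  }
  spread <- min(s, stats::IQR(x) / 1.34)
  if (spread == 0) spread <- s  # pathological: zero IQR but positive sd
  0.9 * spread * length(x)^(-1 / 5)
}

#' Kernel configuration
#'
#' Bundles the Silverman reference bandwidth of a signal segment with the
#' dimensionless scale factor applied to it.  The working kernel width is
#' `sigma = scale_factor * sigma_silverman`.  The default scale factor of 10
#' suppresses spurious kernel harmonics in the correntropy spectrum while
#' retaining the modulation-frequency component.
#'
#' @param x Optional numeric segment from which `sigma_silverman` is
#'   computed; ignored when `sigma_silverman` is given directly.
#' @param sigma_silverman Reference bandwidth (positive, signal units).
#' @param scale_factor Dimensionless multiplier, default 10.
#' @return An object of class `"kernel_config"`: a list with elements
#'   `sigma_silverman`, `scale_factor` and `sigma`.
#' @export
kernel_config <- function(x = NULL, sigma_silverman = NULL,
                          scale_factor = 10) {
  if (is.null(sigma_silverman)) {
    if (is.null(x)) stop("give either 'x' or 'sigma_silverman'", call. = FALSE)
    sigma_silverman <- silverman_bandwidth(x)
  }
  if (sigma_silverman <= 0) stop("'sigma_silverman' must be positive",
                                 call. = FALSE)
  if (scale_factor <= 0) stop("'scale_factor' must be positive",
                              call. = FALSE)
  structure(list(sigma_silverman = sigma_silverman,
                 scale_factor = scale_factor,
                 sigma = scale_factor * sigma_silverman),
            class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  cat(sprintf("kernel_config: sigma = %.6g (= %.6g x Silverman %.6g)\n",
              x$sigma, x$scale_factor, x$sigma_silverman))
  invisible(x)
}

#' Correntropy sequence (uncentered)
#'
#' Gaussian-kernel correntropy of a segment at lags `0..max_lag`,
#' \deqn{V(m) = \frac{1}{N-m} \sum_{n=m+1}^{N}
#'   \kappa_\sigma(x_n - x_{n-m}),}
#' averaging over the `N - m` valid sample pairs at each lag.  `V(0)` equals
#' the kernel at zero by construction.
#'
#' @param x Numeric segment.
#' @param max_lag Maximum lag in samples, must be `< length(x)`.
#' @param kernel A [kernel_config()].
#' @return Numeric vector of length `max_lag + 1`, values in
#'   `(0, gaussian_kernel(0, sigma)]`.
#' @seealso [centered_correntropy()] for the centered sequence used by the
#'   spectral estimator.
#' @export
correntropy <- function(x, max_lag, kernel) {
  stopifnot(inherits(kernel, "kernel_config"))
  N <- length(x)
  if (max_lag >= N) stop("'max_lag' must be smaller than length(x)",
                         call. = FALSE)
  if (max_lag < 1) stop("'max_lag' must be a positive integer", call. = FALSE)
  sigma <- kernel$sigma
  v <- numeric(max_lag + 1)
  v[1L] <- gaussian_kernel(0, sigma)
  for (m in seq_len(max_lag)) {
    v[m + 1L] <- mean(gaussian_kernel(x[(m + 1L):N] - x[1L:(N - m)], sigma))
  }
  v
}

#' Correntropy mean
#'
#' Double average of the kernel over all sample pairs,
#' \deqn{\bar V = \frac{1}{N^2} \sum_{i=1}^N \sum_{j=1}^N
#'   \kappa_\sigma(x_i - x_j),}
#' subtracted from the correntropy sequence to remove the output DC bias
#' before spectral analysis.  Computed block-wise so memory stays
#' O(block x N).
#'
#' @inheritParams correntropy
#' @return Scalar in `(0, gaussian_kernel(0, sigma)]`.
#' @export
correntropy_mean <- function(x, kernel) {
  stopifnot(inherits(kernel, "kernel_config"))
  N <- length(x)
  if (N < 2L) stop("'x' must have at least 2 samples", call. = FALSE)
  sigma <- kernel$sigma
  block <- 1024L
  total <- 0
  for (i0 in seq.int(1L, N, by = block)) {
    i1 <- min(i0 + block - 1L, N)
    total <- total + sum(gaussian_kernel(outer(x[i0:i1], x, "-"), sigma))
  }
  total / N^2
}

#' Centered correntropy sequence
#'
#' The lag sequence driving the correntropy spectral density:
#' \deqn{U(m) = V(m) - \bar V,}
#' the correntropy minus the correntropy mean.  For a constant segment
#' `U(m) = 0` at all lags; centering removes the DC pedestal that the
#' strictly positive kernel otherwise contributes at zero frequency.
#'
#' @inheritParams correntropy
#' @return An object of class `"correntropy_seq"`: a list with elements
#'   `lags` (0..max_lag), `values` (centered `U(m)`), `raw_values` (`V(m)`),
#'   `correntropy_mean`, `kernel` and `n_samples`.
#' @export
centered_correntropy <- function(x, max_lag, kernel) {
  raw <- correntropy(x, max_lag, kernel)
  vbar <- correntropy_mean(x, kernel)
  structure(list(lags = 0:max_lag,
                 values = raw - vbar,
                 raw_values = raw,
                 correntropy_mean = vbar,
                 kernel = kernel,
                 n_samples = length(x)),
            class = "correntropy_seq")
}

#' @export
print.correntropy_seq <- function(x, ...) {
  cat(sprintf(
    "correntropy_seq: %d lags, N = %d, sigma = %.4g, mean = %.4g\n",
    length(x$lags), x$n_samples, x$kernel$sigma, x$correntropy_mean))
  invisible(x)
}
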