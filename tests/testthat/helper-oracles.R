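# Independent oracle implementations -- deliberately naive, used only to
# check the package's vectorized/recursive routines.

# O(N * L) explicit double-loop correntropy with N - m pair averaging.
bf_correntropy <- function(x, max_lag, sigma) {
  N <- length(x)
  k <- function(u) exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  v <- numeric(max_lag + 1)
  v[1] <- k(0)
  for (m in 1:max_lag) {
    acc <- 0
    for (n in (m + 1):N) acc <- acc + k(x[n] - x[n - m])
    v[m + 1] <- acc / (N - m)
  }
  v
}

# O(N^2) explicit double-loop correntropy mean.
bf_correntropy_mean <- function(x, sigma) {
  N <- length(x)
  k <- function(u) exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  acc <- 0
  for (i in 1:N) for (j in 1:N) acc <- acc + k(x[i] - x[j])
  acc / N^2
}

# Direct Toeplitz solve of the Yule-Walker system; returns coefficients in
# the same spectral-denominator sign convention as levinson_yule_walker.
direct_yule_walker <- function(r, p) {
  phi <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
  eps <- r[1] - sum(phi * r[2:(p + 1)])
  list(a = -phi, innovation_variance = eps)
}

# Type-7 (linear interpolation) quantile written out from order statistics.
quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Sample sd / IQR recomputed from first principles for the Silverman check.
manual_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
manual_iqr <- function(x) quantile7(x, 0.75) - quantile7(x, 0.25)

# The package default simulated record used across tests (clean).
fig5_spec <- function(...) simulation_spec(f_c = 1, f_r = 0.2, m = 0.3,
                                           b = 0.3, fs = 100,
                                           duration_s = 120, ...)
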