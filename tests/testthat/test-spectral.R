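polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    j <- i:(i + length(b) - 1)
    out[j] <- out[j] + a[i] * b
  }
  out
}

test_that("Levinson solution equals the direct Toeplitz solve", {
  # white-noise delta sequence: no correlation structure to predict
  m <- levinson_yule_walker(c(1, rep(0, 10)), 7)
  expect_identical(m$coefficients, rep(0, 7))
  expect_identical(m$innovation_variance, 1)
  expect_identical(m$source, "csd")

  # random positive-definite instances (biased acf is always PD)
  set.seed(1)
  worst <- 0
  for (i in 1:1000) {
    y <- rnorm(64)
    r8 <- as.vector(stats::acf(y, lag.max = 8, type = "covariance",
                               plot = FALSE)$acf)
    m <- levinson_yule_walker(r8, 8)
    d <- direct_yule_walker(r8, 8)
    worst <- max(worst, max(abs(m$coefficients - d$a)),
                 abs(m$innovation_variance - d$innovation_variance))
  }
  expect_lt(worst, 1e-10)
  expect_error(levinson_yule_walker(c(0, 1, 2), 2), "zero-lag")
})

test_that("Yule-Walker recovers a known AR(2) from its exact autocorrelation", {
  r <- 0.95
  th <- 2 * pi * 0.2
  phi <- c(2 * r * cos(th), -r^2)
  rho <- as.vector(stats::ARMAacf(ar = phi, lag.max = 20))
  m <- levinson_yule_walker(rho, 2)
  expect_equal(m$coefficients, -phi, tolerance = 1e-8)
  expect_true(m$stable)
})

test_that("MDL order selection: range contract, strong AR(6), white noise", {
  r <- 0.92
  poly <- 1
  for (a in pi * c(0.3, 0.55, 0.8)) {
    poly <- polymul(poly, c(1, -2 * r * cos(a), r^2))
  }
  phi6 <- -poly[-1]
  set.seed(42)
  x <- as.vector(stats::arima.sim(list(ar = phi6), n = 6000))
  rr <- as.vector(stats::acf(x, lag.max = 15, type = "covariance",
                             plot = FALSE)$acf)
  sel <- select_order_mdl(rr, 6000)
  expect_gte(sel, 6)
  expect_lte(sel, 15)
  # oracle MDL curve from the direct Toeplitz solve
  mdl <- vapply(5:6, function(p) {
    d <- direct_yule_walker(rr, p)
    6000 * log(d$innovation_variance) + p * log(6000)
  }, numeric(1))
  expect_lt(mdl[2], mdl[1])

  # white noise: the ln(N) penalty dominates, p_min wins
  for (s in 1:5) {
    set.seed(s)
    w <- rnorm(3000)
    rw <- as.vector(stats::acf(w, lag.max = 15, type = "covariance",
                               plot = FALSE)$acf)
    expect_identical(select_order_mdl(rw, 3000), 5L)
  }
})

test_that("ar_spectrum: flat order-0 limit, pole-frequency peak, variance integral", {
  # order-0 model: flat spectrum sigma^2 * T_s
  m0 <- levinson_yule_walker(c(2.5, 0), 0, source = "psd")
  sp0 <- ar_spectrum(m0, T_s = 0.1, n_freqs = 512)
  expect_equal(sp0$density, rep(2.5 * 0.1, 512))
  expect_equal(range(sp0$freqs), c(0, 5))

  # AR(2) resonance: grid argmax lands at the pole frequency
  r <- 0.95
  phi <- c(2 * r * cos(2 * pi * 0.2), -r^2)
  rho <- as.vector(stats::ARMAacf(ar = phi, lag.max = 4))
  sp <- ar_spectrum(levinson_yule_walker(rho, 2), T_s = 1, n_freqs = 4096)
  step <- diff(sp$freqs[1:2])
  expect_lt(abs(sp$freqs[which.max(sp$density)] - 0.2), 2 * step)
  expect_true(all(sp$density >= 0))
  expect_true(all(diff(sp$freqs) > 0))

  # two-sided trapezoid integral returns the process variance
  sigma2 <- 1
  gamma0 <- sigma2 / (1 - sum(phi * rho[2:3]))
  spv <- ar_spectrum(ppgcsd:::new_ar_model(-phi, sigma2, "psd"), 1, 4096)
  integ <- 2 * sum((spv$density[-1] + spv$density[-4096]) / 2) * step
  expect_equal(integ, gamma0, tolerance = 1e-6)
})

test_that("ar_spectrum peak locations are invariant to amplitude scaling", {
  set.seed(8)
  x <- as.vector(stats::arima.sim(list(ar = c(0.5, -0.7)), n = 2000))
  sp1 <- psd(x, fs = 4)
  sp2 <- psd(64 * x, fs = 4)
  expect_identical(which.max(sp1$density), which.max(sp2$density))
  expect_equal(sp2$density / sp1$density, rep(64^2, 4096))
  c1 <- csd(x, fs = 4)
  c2 <- csd(64 * x, fs = 4)
  expect_identical(which.max(c1$density), which.max(c2$density))
})

test_that("csd of the AM-plus-baseline signal shows both spectral peaks", {
  sig <- simulate_ppg(fig5_spec())
  d1 <- ppgcsd:::decimate_to(sig$samples, 100, 10)
  d2 <- ppgcsd:::decimate_to(d1$samples, d1$fs, d1$fs / 3)
  sp <- csd(d2$samples, d2$fs)
  expect_lt(abs(detect_band_peak(sp, c(0.14, 0.75)) - 0.2), 0.02)
  expect_lt(abs(detect_band_peak(sp, c(0.8, 1.2)) - 1.0), 0.02)
  expect_true(all(sp$density >= 0))
})

test_that("csd of a pure cardiac sinusoid has no respiratory-band structure", {
  x <- cos(2 * pi * 1 * (0:1199) / 10)
  sp <- csd(x, fs = 10)
  band <- sp$freqs >= 0.14 & sp$freqs <= 0.75
  expect_lt(max(sp$density[band]), 0.1 * max(sp$density))
  expect_error(csd(rep(1, 1200), fs = 10), "degenerate")
})

test_that("very large kernel widths shrink the centered-correntropy spectrum", {
  # U(m) -> 0 uniformly as sigma grows, so the absolute spectral peaks
  # collapse by orders of magnitude per decade of kernel scale
  sig <- simulate_ppg(fig5_spec())
  d1 <- ppgcsd:::decimate_to(sig$samples, 100, 10)
  peak <- vapply(c(10, 100, 1000), function(scale) {
    max(csd(d1$samples, d1$fs,
            pipeline_config(scale_factor = scale))$density)
  }, numeric(1))
  expect_lt(peak[2], 0.1 * peak[1])
  expect_lt(peak[3], 0.1 * peak[2])
})

test_that("psd baseline: baseline peak, white-noise flatness, AM sideband identity", {
  # baseline shift puts a direct respiratory line in the PSD
  sig <- simulate_ppg(fig5_spec())
  d1 <- ppgcsd:::decimate_to(sig$samples, 100, 10)
  d2 <- ppgcsd:::decimate_to(d1$samples, d1$fs, d1$fs / 3)
  sp <- psd(d2$samples, d2$fs)
  expect_lt(abs(detect_band_peak(sp, c(0.14, 0.75)) - 0.2), 0.02)

  # white noise: approximately flat under repeated seeds
  for (s in 1:5) {
    set.seed(s)
    spw <- psd(rnorm(2000), fs = 10)
    expect_lt(max(spw$density) / min(spw$density), 3)
  }

  # AM with no baseline: PSD shows sidebands at f_c +/- f_r but no line at
  # f_r; the CSD of the same segment puts the modulation at its true place
  am <- simulate_ppg(simulation_spec(f_c = 1, f_r = 0.2, m = 0.3, b = 0))
  set.seed(7)
  xn <- am$samples + rnorm(length(am$samples), 0, 0.05)
  e1 <- ppgcsd:::decimate_to(xn, 100, 10)
  e2 <- ppgcsd:::decimate_to(e1$samples, e1$fs, e1$fs / 3)
  spp <- psd(e2$samples, e2$fs)
  spc <- csd(e2$samples, e2$fs)
  lm_p <- ppgcsd:::band_local_maxima(spp, c(0.14, 1.4))
  expect_true(any(abs(lm_p$freq - 0.8) < 0.05))   # lower sideband
  expect_true(any(abs(lm_p$freq - 1.2) < 0.05))   # upper sideband
  expect_false(any(abs(lm_p$freq - 0.2) < 0.05))  # no true-location line
  expect_lt(abs(detect_band_peak(spc, c(0.14, 0.75)) - 0.2), 0.01)
})

test_that("csd/psd discriminate the AM modulation frequency across seeds", {
  am <- simulate_ppg(simulation_spec(f_c = 1, f_r = 0.2, m = 0.3, b = 0))
  csd_hits <- psd_hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    xn <- am$samples + rnorm(length(am$samples), 0, 0.05)
    e1 <- ppgcsd:::decimate_to(xn, 100, 10)
    e2 <- ppgcsd:::decimate_to(e1$samples, e1$fs, e1$fs / 3)
    grid_step <- (e2$fs / 2) / 4095
    fcs <- detect_band_peak(csd(e2$samples, e2$fs), c(0.14, 0.75))
    fps <- detect_band_peak(psd(e2$samples, e2$fs), c(0.14, 0.75))
    # a hit = within 0.01 Hz of the modulation frequency (roughly 25 grid
    # steps; misses land far away, at band edges or sidebands)
    if (abs(fcs - 0.2) <= 0.01) csd_hits <- csd_hits + 1L
    if (abs(fps - 0.2) <= 0.01) psd_hits <- psd_hits + 1L
  }
  expect_gte(csd_hits, 18L)
  expect_lt(psd_hits, csd_hits)
})
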