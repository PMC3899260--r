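test_that("simulation_spec validates its invariants", {
  expect_error(simulation_spec(f_c = 0.2, f_r = 0.3), "f_r")
  expect_error(simulation_spec(f_c = 1, fs = 1.5), "fs")
  expect_error(simulation_spec(m = 1.2), "m")
  expect_error(simulation_spec(n_outliers = 1e9), "n_outliers")
})

test_that("simulate_ppg is the AM-plus-baseline closed form", {
  spec <- simulation_spec(f_c = 1, f_r = 0.2, m = 0.3, b = 0.25,
                          fs = 50, duration_s = 30, n_outliers = 0)
  sig <- simulate_ppg(spec)
  expect_s3_class(sig, "sampled_signal")
  expect_length(sig$samples, round(50 * 30))
  t <- (0:(length(sig$samples) - 1)) / 50
  expected <- (1 + 0.3 * cos(2 * pi * 0.2 * t)) * cos(2 * pi * 1 * t) +
    0.25 * cos(2 * pi * 0.2 * t)
  expect_identical(sig$samples, expected)
  expect_lte(max(abs(sig$samples)), 1 + 0.3 + 0.25)
  expect_equal(attr(sig, "truth"), list(f_c = 1, f_r = 0.2))
  # deterministic: same spec twice gives bit-identical samples
  expect_identical(simulate_ppg(spec)$samples, sig$samples)
})

test_that("degenerate AM (m = b = 0) has no respiratory-band content", {
  spec <- simulation_spec(f_c = 1, f_r = 0.2, m = 0, b = 0,
                          fs = 100, duration_s = 60)
  x <- simulate_ppg(spec)$samples
  X <- abs(stats::fft(x)) / length(x)
  freqs <- (seq_along(X) - 1) * 100 / length(x)
  rr_bins <- freqs >= 0.14 & freqs <= 0.75
  carrier_bin <- which.min(abs(freqs - 1))
  expect_lt(max(X[rr_bins]), 1e-10 * X[carrier_bin])
})

test_that("clean-signal DFT has lines only at f_r, f_c and f_c +/- f_r", {
  # 60 s at integer periods of both frequencies: no leakage
  spec <- simulation_spec(f_c = 1, f_r = 0.2, m = 0.3, b = 0.3,
                          fs = 20, duration_s = 60)
  x <- simulate_ppg(spec)$samples
  n <- length(x)
  X <- abs(stats::fft(x)) / n
  freqs <- (0:(n - 1)) * 20 / n
  # bin index k corresponds to k/60 Hz; lines at 0.2, 0.8, 1.0, 1.2 Hz
  line_bins <- c(12, 48, 60, 72)
  is_line <- (0:(n - 1)) %in% c(line_bins, n - line_bins)
  expect_lt(max(X[!is_line]), 1e-10)
  # expected two-sided amplitudes: b/2 at f_r, 1/2 at f_c, m/4 at sidebands
  amp_at <- function(f) X[which.min(abs(freqs - f))]
  expect_equal(amp_at(0.2), 0.3 / 2, tolerance = 1e-12)
  expect_equal(amp_at(1.0), 1 / 2, tolerance = 1e-12)
  expect_equal(amp_at(0.8), 0.3 / 4, tolerance = 1e-12)
  expect_equal(amp_at(1.2), 0.3 / 4, tolerance = 1e-12)
})

test_that("inject_outliers honors count, range and reproducibility", {
  spec <- fig5_spec()
  sig <- simulate_ppg(spec)
  clean <- sig$samples
  noisy <- inject_outliers(sig, 100, seed = 3)
  idx <- attr(noisy, "outlier_idx")
  expect_length(idx, 100)
  expect_identical(idx, sort(idx))
  changed <- which(noisy$samples != clean)
  expect_true(all(changed %in% idx))
  expect_length(changed, 100)  # uniform draws never coincide in practice
  mu <- mean(clean); s <- sd(clean)
  expect_true(all(noisy$samples[idx] >= mu - 5 * s &
                  noisy$samples[idx] <= mu + 5 * s))
  # untouched samples are bit-identical
  expect_identical(noisy$samples[-idx], clean[-idx])
  # n_outliers = 0 is the identity
  same <- inject_outliers(sig, 0)
  expect_identical(same$samples, clean)
  # reproducible given the seed, different across seeds
  expect_identical(inject_outliers(sig, 100, seed = 3)$samples,
                   noisy$samples)
  expect_false(identical(inject_outliers(sig, 100, seed = 4)$samples,
                         noisy$samples))
  expect_error(inject_outliers(sig, length(clean) + 1), "exceeds")
})

test_that("inject_outliers leaves the session RNG state alone", {
  set.seed(123)
  before <- .Random.seed
  invisible(inject_outliers(simulate_ppg(fig5_spec()), 50, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("simulate_ppg_noisy composes simulation and corruption", {
  spec <- simulation_spec(n_outliers = 25, seed = 7)
  sig <- simulate_ppg_noisy(spec)
  expect_length(attr(sig, "outlier_idx"), 25)
  expect_equal(attr(sig, "truth"), list(f_c = 1, f_r = 0.2))
})
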