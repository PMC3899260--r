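# ppgcsd

Simultaneous estimation of respiratory rate (RR) and heart rate (HR) from a
single photoplethysmogram (PPG) channel, using the **correntropy spectral
density (CSD)**.

## Who this is for

The PPG from a pulse oximeter carries the cardiac pulse (AC component),
amplitude-modulated and baseline-shifted by respiration. Estimating RR from
it would turn every pulse oximeter into a two-vital-sign monitor without
extra sensors. Conventional power spectral density (PSD) analysis sees the
respiratory amplitude modulation only as sidebands around the cardiac peak
and is fragile against the impulsive artifacts common in ambulatory
recordings. The CSD — the spectral density of the *centered correntropy*
sequence — places the modulation frequency at its true spectral position
and bounds the influence of outlying samples through a Gaussian kernel.
This package is for researchers in biomedical signal processing who want a
complete, tested reference implementation of that estimator, its PSD
baseline, a synthetic PPG generator, and the matching evaluation tools.

## The method

For a windowed segment `x_1..x_N`, the correntropy sequence and its mean
are

    V(m)  = 1/(N-m) * sum_n  k_sigma(x_n - x_{n-m})
    Vbar  = 1/N^2   * sum_i sum_j  k_sigma(x_i - x_j)

with the Gaussian kernel `k_sigma(u) = exp(-u^2 / (2 sigma^2)) /
(sqrt(2 pi) sigma)` and `sigma = 10 x` Silverman's rule-of-thumb bandwidth
of the segment. The centered sequence `U(m) = V(m) - Vbar` is fitted with
an autoregressive (AR) model via the Yule-Walker equations
(Levinson-Durbin), the order chosen on 5..15 by Rissanen's minimum
description length, and the spectrum evaluated as

    S(f) = sigma_e^2 T_s / | 1 + sum_k a_k exp(-i 2 pi f k T_s) |^2 .

Rates are tracked over sliding 60-s or 120-s windows with 50 % overlap: the
HR is the dominant spectral peak in the cardiac band (0.5-3 Hz, i.e.
30-180 beats/min); the window is then low-pass filtered 0.1 Hz below the
detected HR (zero-phase Butterworth), and the RR is the dominant remaining
peak in the respiratory band (0.14-1 Hz, 8.4-60 breaths/min), with
harmonic-exclusion rules for elevated RR. The PSD baseline runs the same
AR machinery on the biased sample autocorrelation.

## Worked example

```r
library(ppgcsd)

# 120 s of synthetic PPG: 1 Hz cardiac carrier (60 beats/min), 0.2 Hz
# respiratory modulation (12 breaths/min), AM index 0.3, baseline 0.3
sig <- simulate_ppg(simulation_spec(f_c = 1, f_r = 0.2, m = 0.3, b = 0.3,
                                    fs = 100, duration_s = 120))
estimate_rates(sig, pipeline_config(window_s = 120))
#>   window_center_s    hr_hz   hr_bpm     rr_hz  rr_brpm       flags
#> 1              60 1.001221 60.07326 0.2018722 12.11233 regularized
```

One 120-s window, centered at 60 s: the cardiac peak is found at
1.0012 Hz (60.07 beats/min) and the respiratory peak at 0.2019 Hz
(12.11 breaths/min) — both within a small fraction of a cycle/min of the
ground truth. The `regularized` flag records that the nearly
deterministic, low-passed respiratory-stage window needed a small ridge on
the zero lag of its correntropy sequence (routine for noiseless synthetic
signals).

With 100 impulsive outliers injected, the same call still returns
60.07 beats/min and ~12.1 breaths/min — the robustness property that
motivates the correntropy kernel:

```r
noisy <- inject_outliers(sig, n_outliers = 100, seed = 1)
estimate_rates(noisy)[, c("hr_bpm", "rr_brpm")]
#>     hr_bpm  rr_brpm
#> 1 60.07326 12.08791
```

A command-line interface covers the same flow
(`inst/cli/ppgcsd.R estimate|simulate|evaluate|sweep-kernel`); evaluation
utilities (`rms_error`, `cohort_summary`, `bland_altman`, `pair_rates`)
score estimates against reference rate tables.

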