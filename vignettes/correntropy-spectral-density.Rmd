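---
title: "Correntropy spectral density for simultaneous RR and HR estimation from the PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correntropy spectral density for simultaneous RR and HR estimation from the PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgcsd)
```

## The signal model

A photoplethysmogram is dominated by the cardiac pulse, an oscillation at
the heart rate $f_c$. Respiration at rate $f_r$ leaves two usable imprints:
a slow **baseline shift** synchronized with each breath, and **amplitude
modulation** (AM) of the pulse. The package's generator reproduces exactly
these two effects:

$$x(t) = \bigl(1 + m\cos(2\pi f_r t)\bigr)\cos(2\pi f_c t)
       + b\cos(2\pi f_r t),$$

with modulation index $m$ and baseline amplitude $b$, optionally corrupted
by impulsive outliers (uniform draws within mean $\pm 5$ sd replacing
randomly chosen samples). Respiratory sinus arrhythmia — frequency
modulation of the carrier — is deliberately **not** modelled; it is a third,
age-dependent respiratory effect that the estimator does not rely on.

Spectrally, the clean signal has lines at $f_r$ (from $b$), $f_c$, and the
AM sidebands $f_c \pm f_r$ — *not* at $f_r$ from the AM term. A
second-order spectrum therefore sees the modulation only as sidebands; when
the baseline is weak, the true respiratory frequency is simply absent from
the PSD. This is the gap the correntropy spectrum closes.

## Centered correntropy and its spectrum

For a segment $x_1,\dots,x_N$ the correntropy sequence, its mean, and the
centered sequence are

$$V(m) = \frac{1}{N-m}\sum_{n=m+1}^{N}\kappa_\sigma(x_n - x_{n-m}),\qquad
\bar V = \frac{1}{N^2}\sum_{i,j}\kappa_\sigma(x_i - x_j),\qquad
U(m) = V(m) - \bar V,$$

with the density-normalized Gaussian kernel $\kappa_\sigma$. Centering
removes the DC pedestal the strictly positive kernel would otherwise put at
zero frequency. Two properties drive everything else:

* the kernel's even nonlinearity mixes spectral lines, so an AM signal's
  $U(m)$ contains a component at the modulation frequency itself;
* pairs involving an outlying sample contribute $\kappa_\sigma(\cdot)
  \approx 0$ rather than an unbounded product, so impulsive noise barely
  perturbs $U(m)$.

The lag-$m$ average uses the $N-m$ valid pairs (rather than a fixed $N$
denominator) so that the short lag range feeding the AR fit is not tapered.

**Kernel sizing.** $\sigma$ = `scale_factor` × Silverman's robust
rule-of-thumb bandwidth $0.9\min(\mathrm{sd},\mathrm{IQR}/1.34)N^{-1/5}$,
recomputed *per window and per stage* from the samples actually entering
the correntropy — windows are the stationarity unit, and the resulting
scale equivariance makes every rate estimate exactly invariant under
amplitude rescaling of the record. The default `scale_factor = 10`
suppresses spurious kernel harmonics while keeping the modulation
component; `sweep_kernel_scale()` reproduces the calibration experiment
(RR error at scales 1, 5, 10, 20) on a simulated cohort. As
$\sigma \to \infty$, $U(m) \to 0$ uniformly and the spectral peaks collapse
in absolute height — at very large scales only the second-order structure
survives, so the CSD loses its AM advantage and degrades toward the PSD.

## AR parameterization

$U(m)$ at lags $0..15$ is fitted with an autoregressive model through the
Yule–Walker equations, solved by the Levinson–Durbin recursion (the PSD
baseline runs the identical machinery on the biased sample autocorrelation
of the mean-removed window). The order is selected on $[5, 15]$ by
Rissanen's minimum description length,
$\mathrm{MDL}(p) = N\ln\varepsilon_p + p\ln N$, with $\varepsilon_p$ the
Levinson prediction-error power, $N$ the post-decimation window sample
count, and ties broken toward the smaller order. The spectrum is

$$S(f) = \frac{\sigma_e^2\,T_s}{\bigl|1 + \sum_{k=1}^{p}
a_k e^{-i2\pi f k T_s}\bigr|^2}$$

on a 4096-point grid over $[0,$ Nyquist$]$ — a grid step of
$\le 0.0012$ Hz at the cardiac-stage rate, far below the 0.1 Hz tolerances
used in the peak logic.

**Regularization.** Centered correntropy is not guaranteed positive
definite, and for nearly deterministic low-passed windows its Toeplitz
matrix is close to rank deficient (observed prediction-error collapse by
order 4–5). When the recursion fails inside the order range, a relative
ridge is added to the zero lag, escalating tenfold from $10^{-8}$ and
capped at $10^{-2}$; MDL then selects among the orders the recursion
supports. The cap matters: a ridge large enough to force validity through
order 15 measurably distorts peak locations, while the capped ridge plus
order restriction does not. Affected windows carry a `regularized` flag; a
sequence with no valid order at all yields a flagged, rate-absent window.

## The two-stage pipeline

Per sliding window (60 s or 120 s, 50 % overlap, trailing partial window
dropped):

1. decimate the record to the **cardiac stage** rate (default 10 Hz,
   integer factor, zero-phase anti-alias filtering);
2. CSD (or PSD) of the window; HR = dominant peak in 0.5–3 Hz;
3. zero-phase low-pass (4th-order Butterworth, forward–backward) at
   $f_{hr} - 0.1$ Hz;
4. decimate by a further factor 3 to the **respiratory stage** rate
   (default 10/3 Hz);
5. CSD (or PSD) again; RR = dominant respiratory-band peak after the
   exclusion rules below.

**Why two decimation stages.** Yule–Walker pole estimation degrades badly
for heavily oversampled narrowband components: at a 25 Hz effective rate a
0.2 Hz respiratory pole sits at angle 0.05 rad, where the 16-lag Toeplitz
system is too ill-conditioned to place it, and the respiratory peak is
systematically lost to the residual carrier. Running the cardiac detection
at ~10 Hz and the respiratory detection at ~3.3 Hz keeps both pole angles
in a well-conditioned range while the Nyquist limits still clear the band
tops (5 Hz vs 3 Hz, 1.67 Hz vs 1 Hz). Both rates are configuration
parameters (`hr_rate`, `rr_decim`).

**Peak picking.** The band peak is the highest-density *interior local
maximum* in the band; if none exists, the band-restricted argmax; ties go
to the lower frequency.

**Harmonic exclusion.** The RR candidate list (respiratory-band local
maxima, strongest first) passes through:

* a **cardiac-residual guard**: candidates within ±0.1 Hz of the detected
  $f_{hr}$ are discarded outright. The 0.1-Hz-below-HR cutoff leaves a
  residual carrier line whenever $f_{hr} \lesssim 1.1$ Hz, and a
  respiratory "estimate" at the just-filtered cardiac frequency is never
  genuine;
* only when the remaining top candidate exceeds the elevated-RR threshold
  (0.75 Hz = 45 breaths/min): candidates within ±0.1 Hz of $f_{hr}/2$ are
  discarded, and a candidate within ±0.1 Hz of $f_{hr} - g$ for an already
  retained stronger candidate $g$ (the lower AM sideband image) is
  discarded. If everything is excluded the original top candidate is
  returned, flagged `harmonic_excluded`.

The ±0.1 Hz tolerance mirrors the only frequency tolerance the filtering
stage itself uses, and is configurable. The low-pass order stays at 4
(forward–backward, effective 8th-order magnitude): with the cutoff only
0.1 Hz below the carrier, *no* practical Butterworth order suppresses the
carrier completely (the two-pass response at $f_{hr}=1$ Hz is ≈10 dB), and
high orders at low normalized cutoffs become numerically fragile — the
residual guard above is the robust complement.

## Evaluation

Per-window estimates are paired with reference rates by taking the median
of the instantaneous reference values inside each window
(`pair_rates()`; empty windows are dropped and counted). Accuracy is the
unnormalized RMS error per record, summarized across a cohort by median
and quartiles (type-7 linear interpolation — stated because quartile
conventions differ). Agreement uses Bland–Altman with differences oriented
`estimated − reference` and limits at bias ± 1.96 sd (sample sd).

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
signals: 120 s records at 100 Hz for the worked example and its 20
outlier-corrupted replicates, a 3×3 grid of (cardiac, respiratory)
frequency pairs, 480 s records for the multi-window and kernel-sweep
checks, and 1000 small random instances for the Levinson/Toeplitz
equivalence. Everything is seeded; the pipeline itself contains no
randomness, so identical input and configuration give identical estimates.

## Known limitations

* **AR order cap vs clean multi-line signals.** With the order capped at
  15 (seven pole pairs), the correntropy of a *noiseless* AM-plus-baseline
  signal carries more deterministic lines — kernel harmonics, sidebands,
  intermodulation products — than the model can represent, and the
  truncation displaces the carrier peak by up to ~1 % for unfavorable
  frequency pairs (allowing order 20 removes the bias almost entirely).
  Real PPG noise floors absorb the weak lines and soften this; the
  pathologically clean synthetic grid is the worst case. Peaks are still
  identified correctly; it is the last fraction of a percent of peak
  *placement* that is limited.
* **Window length.** 60 s minimum; rate changes faster than half a window
  are smeared, and the estimator reports one value per window with no
  trajectory smoothing (a hybrid median filter over time would be a
  natural extension and is intentionally out of scope).
* **Coincident lines.** When the carrier falls on a low harmonic of the
  respiratory frequency (e.g. $f_c = 4 f_r$), kernel-generated harmonics
  interfere with the carrier peak; the bias stays well under the
  band-assignment scale but is visible at fine tolerances.
* **What the simulator does not emulate.** Real PPG morphology
  (non-sinusoidal pulse shape), respiratory sinus arrhythmia, baseline
  wander unrelated to respiration, sensor saturation, and the artifact
  structure of ambulatory recordings. Passing the synthetic checks
  demonstrates the spectral mechanics and outlier robustness, not clinical
  accuracy; validation against annotated clinical recordings (e.g. the
  Capnobase benchmark) is the corresponding integration-level exercise and
  needs that external data.
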