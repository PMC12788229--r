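---
title: "Estimating respiratory rate from Wi-Fi channel state information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from Wi-Fi channel state information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csibreath)
```

## The problem and the model

A Wi-Fi receiver continuously estimates a complex channel coefficient for
each OFDM subcarrier (K = 256 at 80 MHz). A person breathing between
transmitter and receiver perturbs the multipath geometry, so the
*magnitudes* of those coefficients carry a small quasi-periodic modulation
at the breathing frequency on a subject- and geometry-dependent subset of
subcarriers. The phase of commodity-chipset CSI is usually too corrupted to
use, which is why this package works on magnitudes only.

`csibreath` converts a T x K magnitude stream, sampled at a nominal packet
rate of 50 Hz, into a 1 Hz respiratory-rate (RR) series. The core
assumptions are:

* breathing is the dominant *coherent* low-frequency signal shared across
  several subcarriers, while noise and drift are mostly independent
  between subcarriers — which is what makes per-window PCA an effective
  spatial filter;
* the physiological rate lies in 5–35 brpm (0.083–0.583 Hz);
* within a 30 s window the rate is approximately constant, and across
  windows it drifts slowly (a paced protocol changes by at most 3 brpm
  every two minutes).

## Pipeline stages and their parameters

**Windowing.** 30 s windows advancing by 1 s. An estimate stamped `t`
summarises the interval `(t − 30, t]`; every module shares this
trailing-edge convention, including the airflow reference and the
ground-truth alignment used in benchmarks (`windowed_truth()`). The window
length fixes the FFT resolution at 1/30 Hz = 2 brpm, which lower-bounds the
achievable accuracy of the spectral estimator.

**Component quality index (selection).** Each principal component is scored
by `CQI = Γσ · Γ_SNR · Γ_peak`:

* `Γσ` retains ranks up to the elbow of the cumulative explained-variance
  curve — the smallest rank whose *next* component adds less than 1%
  variance. At least one component is always retained. The 1% gradient is
  the natural scale for K = 256: independent per-subcarrier noise spreads
  into components of roughly 0.4% each, so the rule cuts just above the
  noise floor. (With very few subcarriers the noise eigenvalues can each
  exceed 1% and the retained set grows; the index is still well defined.)
* `Γ_SNR` is the fraction of one-sided spectral *magnitude* (mean removed,
  no taper) inside 5–35 brpm. Magnitude rather than power is the default
  because the index is written as a ratio of |FFT| sums; power spectra are
  available via `snr_power = TRUE` and are slightly more forgiving of
  spectral leakage.
* `Γ_peak` is 1 only when the dominant spectral peak lies at or above
  5 brpm (inclusive). Slow 1/f-like drift carries high variance *and* can
  carry high in-band energy fractions, so this binary guard is what
  actually rejects it. It is computed before band-pass filtering, since
  filtering would trivially move every peak in band.

The five highest-CQI components are kept (ties broken by variance rank).
If every CQI is zero — a degenerate or purely artefactual window — the five
highest-variance components are used and the window is flagged
`low_quality`.

**Filtering.** Selected components pass a 4th-order Butterworth high-pass
at the lower band edge and then a 4th-order low-pass at the upper edge,
each applied forward–backward. Zero-phase filtering matters because
breath-onset *timestamps* feed the rate formula; the two-pass application
doubles the effective stopband attenuation, which is documented rather than
compensated. The default band is 5–35 brpm; a 6–33 brpm preset
(`band_preset = "experimental"`) matches a paced 6-to-33 protocol. The two
bands are deliberately both available and not reconciled.

**Breath counting (BSSF).** The slope sum transform — a 1 s sliding box sum
of positive first differences — converts each inhalation into a rise.
Onsets are upward crossings of an adaptive threshold (0.5 x the median
height of the slope-sum local maxima in the window), searched back to the
start of the rise, with a refractory period of `60/f_max` ≈ 1.7 s. The box
width, threshold fraction and refractory period scale a pulse-waveform
onset detector to breath timescales; all three are exposed in the
configuration. The rate is `(N − 1)/(t_last − t_first) · 60`: the same
N − 1 intervals convention is used for airflow peaks, deliberately, so the
two branches are comparable (counting N peaks over the span of N − 1
intervals would overestimate by one cycle per window).

**Spectral peak.** Hann taper, FFT, largest magnitude *within the band* —
restricting the argmax keeps residual drift from winning. Windows whose
in-band spectrum is indistinguishable from zero give an invalid estimate
rather than a number.

**Combination and SQI.** The two estimates are averaged; if exactly one is
defined it is used alone but the agreement factor is forced to 0, which is
the conservative reading of an agreement test with a missing party. The
signal quality index multiplies the pre-filter SNR index, the agreement
factor (1 iff |RR_FFT − RR_breath| ≤ 4 brpm, boundary inclusive), and the
spectral purity index.

**Spectral purity.** `SPI = m2² / (m0 · m4)` over the one-sided power
spectrum with frequency in radians per sample; Cauchy–Schwarz bounds it in
[0, 1], a single tone gives 1, and a perfectly flat spectrum gives exactly
5/9 (both landmarks are asserted in the tests; the popular claim that white
noise gives ≈ 0 is not what the moment ratio evaluates to under this
normalisation). Taken literally at a 50 Hz sampling rate the index is
useless for breathing: a 0.2 Hz tone sits at ω ≈ 0.025 rad/sample, so the
ω⁴ weighting lets any residual near-Nyquist noise — even 60 dB down —
dominate the fourth moment, and genuine respiratory components score near
zero. The pipeline therefore computes the moments only up to twice the
upper band edge, rescaling ω so that range spans [0, π] — exactly the index
an ideal decimation to ~2.3 Hz would give. The cap is exposed as `f_cap`
on `spectral_purity()`; the uncapped form remains the default of the bare
function.

**Fusion.** Each component rank keeps a scalar random-walk Kalman filter
across windows (process variance 0.1 brpm²/step, matching protocol
dynamics; initial error variance `((band width)/4)²`; measurement variance
`1/SQI²` brpm²). Per window, sources with a valid candidate and positive
SQI are updated and combined by inverse-variance weighting with
`σ² = r/SQI²`, `r` being the posterior error variance (an innovation-based
variant sits behind `residual = "innovation"`). The inverse-variance mean
is algebraically identical to the product-of-variances weighting sometimes
written for multi-source fusion; the tests assert the equivalence to 1e−10
against an independently coded product form. Component identity across
windows is the post-selection rank — a label-switching approximation,
acknowledged as such.

**Harmonic folding.** PCA on a non-sinusoidal breath with subcarrier phase
lags separates the signal into Fourier modes: the fundamental occupies the
top-variance quadrature pair and its harmonics appear in lower-variance
components as spectrally *pure* tones. On low-noise sessions those harmonic
components can out-score the (leakage-smeared) fundamental on both SNR and
SPI, and quality-weighted fusion then locks onto twice the true rate. The
fusion stage therefore re-interprets a source whose RR lies within the
agreement tolerance of 2x or 3x a usable higher-variance source's RR as
that harmonic and divides it down before the Kalman update
(`harmonic_tolerance`, 0 disables). Variance rank arbitrates direction:
the fundamental always carries more energy than its harmonics.

## The reference branch

The airflow reference mirrors clinical practice: an 8th-order Butterworth
band-pass (5–35 brpm, zero-phase), per-window breath-peak detection, and
the same windowing. Peak detection collects alternating extrema, computes
the third quartile Q3 of adjacent peak–trough vertical differences, and
recursively discards peaks closer than 0.3·Q3 to their nearest trough —
after each removal the two flanking troughs merge (the deeper survives) and
separations are re-evaluated until stable; termination is guaranteed
because the peak count strictly decreases. Q3 is computed per window, not
globally. Windows deviating from the paced metronome rate by strictly more
than 4 brpm are excluded from scoring (a deviation of exactly 4 is kept);
the exclusion is idempotent.

## The synthetic session generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

* **Protocol**: a metronome staircase, by default 6 → 33 brpm in 3 brpm
  steps held 120 s each (20 minutes).
* **Waveform**: raised-cosine breath cycles with an inhale fraction of 0.4,
  phase-continuous across rate changes. The asymmetry gives the harmonics
  a real chest/nasal signal has, which is precisely what exercises the
  peak detectors and the harmonic-folding guard. Metronome compliance is
  imperfect: the instantaneous rate carries a bounded random walk
  (default ±0.5 brpm — of the order of the sub-brpm wander real paced
  subjects show).
* **CSI coupling**: a random 20% of subcarriers (moderate profile) receive
  the waveform with log-normal gains (median 0.5 magnitude units) and a
  phase lag uniform over one breath cycle; baselines are log-normal around
  20. The lag is applied on the phase accumulator, not as a time shift, so
  the modulation stays synchronous with ground truth at schedule steps.
* **Noise**: per-subcarrier white noise (sd 0.25), sub-0.05 Hz 1/f-like
  drift (integrated white noise, low-passed; sd 0.3), and two 3 s motion
  bursts of high-variance noise across all subcarriers (sd 2).
* **Airflow**: the time derivative of displacement (nasal pressure tracks
  flow), unit peak amplitude, at 32 Hz, with additive noise and slow
  baseline wander.
* All randomness flows from one explicit seed through an isolated RNG
  scope; identical parameters and seed give bit-identical sessions.

The `clean` and `noisy` profiles bracket the moderate one (stronger/denser
coupling with negligible noise, and sparser/weaker coupling with heavier
noise and four bursts, respectively).

What the generator does *not* emulate: RF propagation physics, complex or
phase CSI, packet loss, multi-person scenes, posture changes, or the
long-tailed interference of real deployments. Passing the synthetic
benchmarks therefore demonstrates that the algorithm chain is implemented
coherently and recovers rates under the stated noise model — not that the
accuracy transfers to real hardware.

## Numerical choices and degenerate inputs

* Per-window PCA uses the eigendecomposition of the window covariance;
  inside the pipeline the covariance is updated incrementally between
  29/30-overlapping windows and recomputed from scratch every 200 windows
  to bound floating-point drift. Component signs are normalised to
  non-negative skewness so outputs are deterministic.
* A zero-variance window yields a degenerate component set with all CQIs
  forced to zero; constant signals yield empty peak/onset trains, not
  errors; windows with fewer than two peaks or onsets are invalid, never
  interpolated.
* Fusion windows with no usable source emit `valid = FALSE` while all
  Kalman filters take predict-only steps; fused estimates outside the
  filter band are also invalidated.
* Benchmarks at desk scale: the shipped acceptance script runs three full
  20-minute, 256-subcarrier sessions (about 1171 windows each); unit tests
  use shorter schedules and fewer subcarriers so the whole suite stays in
  a few minutes.

## Known limitations

* Component tracking across windows is by quality rank, not by subspace
  continuity; rapid changes in which subcarriers couple to breathing can
  momentarily scramble source identities (the Kalman filters absorb most
  of this).
* The harmonic-folding guard assumes the fundamental out-powers its
  harmonics — true for chest-displacement physics, but a pathological
  source distribution could fold a genuine fast breather near an integer
  multiple of a slow artefact.
* At 6 brpm only three breath cycles fit a window: breath counting loses
  precision and the high-pass edge sits close to the fundamental, so
  low-rate accuracy is intrinsically worse — visible in the banded
  reports.
* The 2 brpm FFT bin at 30 s windows floors the spectral estimator's
  granularity; longer windows would trade responsiveness for resolution.
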