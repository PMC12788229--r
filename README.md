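# csibreath

Contactless respiratory-rate (RR) estimation from the subcarrier magnitudes
of a Wi-Fi channel state information (CSI) stream.

Human breathing displaces the chest and abdominal wall, which perturbs the
multipath propagation of a nearby Wi-Fi link. In an OFDM channel the
receiver estimates a complex channel coefficient per subcarrier (K = 256 at
80 MHz bandwidth); the magnitudes of those coefficients, sampled at the
packet rate (nominally 50 Hz), carry a small quasi-periodic respiratory
modulation on a subject-dependent subset of subcarriers. `csibreath`
implements a full pipeline that turns such a T x K magnitude stream into a
1 Hz RR series, plus everything needed to validate it without hardware: a
synthetic session generator, an airflow-based reference-RR pipeline, and
Bland-Altman-style agreement reporting.

## The method

For each 30 s window (sliding by 1 s, trailing-edge timestamps):

1. **PCA** of the mean-removed W x K window, components ordered by
   eigenvalue.
2. **Component quality index.** Each component *i* is scored by
   `CQI_i = Γσ_i · Γ_SNR_i · Γ_peak_i`, where
   - `Γσ_i ∈ {0,1}`: 1 for ranks up to the cumulative-explained-variance
     elbow (the smallest rank whose next component adds < 1% variance);
   - `Γ_SNR_i ∈ [0,1]`: fraction of spectral magnitude inside the
     physiological band 5-35 brpm (0.083-0.583 Hz);
   - `Γ_peak_i ∈ {0,1}`: 1 when the dominant spectral peak lies at or above
     5 brpm (guards against 1/f drift).
   The five components with the highest CQI proceed.
3. **Dual RR estimation** per selected component after zero-phase Butterworth
   band-pass filtering (high-pass then low-pass):
   - breath counting: `RR_breath = (N_onsets − 1)/(t_last − t_first) · 60`
     with onsets from a box slope sum function (BSSF) detector;
   - spectral peak: `RR_FFT = 60 · argmax |FFT|` over the band after a Hann
     taper (resolution 1/30 Hz = 2 brpm);
   - combined: `RR = (RR_breath + RR_FFT)/2`.
4. **Signal quality index** `SQI_i = Γ_SNR_i · Γ_agree_i · Γ_SPI_i`:
   the pre-filter SNR index, an agreement factor (1 iff the two estimators
   agree within 4 brpm), and the spectral purity index
   `SPI = m2²/(m0·m4)` from power-spectral moments.
5. **Fusion.** Each component rank runs a scalar random-walk Kalman filter
   over its combined estimates (measurement variance ∝ 1/SQI²); per window
   the filtered estimates are combined by inverse-variance weighting with
   `σ_i² = r_i / SQI_i²`, where `r_i` is the Kalman residual error.
   Zero-SQI sources are excluded; sources reporting an integer multiple of
   a stronger source's RR are folded down to the fundamental.

Reference RR comes from a nasal-airflow pressure trace: 8th-order
Butterworth band-pass (5-35 brpm), quartile-thresholded breath-peak
detection (peaks within 0.3·Q3 of the nearest trough are recursively
discarded), `(N−1)/span` rate over the same 30 s windows, and a
metronome-compliance exclusion that drops windows deviating more than
4 brpm from the paced rate.

## Worked example

Generate a paced-protocol session (6 to 33 brpm, +3 brpm every 120 s, 20
minutes), run the pipeline, and score it against the generator's ground
truth:

```r
library(csibreath)

sched <- make_schedule()                 # 6:3:33:120 - 10 levels, 20 min
ses   <- synth_session(sched, profile = "moderate", seed = 1)
res   <- run_pipeline(ses$csi)
res
#> <csibreath_result> synthetic-1: 1171 windows, 1171 valid (100.0%), 71 s

truth <- windowed_truth(ses$waveform$truth)
report <- agreement_metrics(align_series(res$fused, truth))
report
#> <agreement_report>
#>   n windows : 1171
#>   MAE       : 0.41 brpm
#>   RMSE      : 0.51 brpm
#>   r-squared : 0.997
#>   bias      : -0.21 brpm (LoA -1.12 to 0.71)
#>   within 2  : 100.0%
```

The MAE of 0.41 brpm sits near the floor set by the 2 brpm FFT bin width of
a 30 s window; the negative bias reflects the Kalman filter's slight lag on
a rising staircase protocol. `autoplot(report)` draws the Bland-Altman
plot, `autoplot(res$fused)` the RR trace, and `glance(report)` /
`tidy(report)` give the metrics as tibbles. The airflow branch works the
same way:

```r
ref <- reference_rr(ses$airflow) |> apply_compliance_exclusion(sched)
glance(agreement_metrics(align_series(ref, truth)))
#> # A tibble: 1 x 8
#>      mae   rmse r_squared    bias loa_low loa_high rr2brpm     n
#>    <dbl>  <dbl>     <dbl>   <dbl>   <dbl>    <dbl>   <dbl> <int>
#> 1 0.0450 0.0879     1.000 0.00574  -0.166    0.178     100  1170
```

A thin command-line front end with `synth`, `reference`, `estimate`,
`evaluate` and `bench` subcommands is installed at
`system.file("cli", "csibreath", package = "csibreath")`.

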