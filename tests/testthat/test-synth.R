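test_that("generators are bit-identical under a fixed seed", {
  sched <- make_schedule(12, 3, 15, 30)
  w1 <- synth_respiratory_waveform(sched, jitter = 1, seed = 7)
  w2 <- synth_respiratory_waveform(sched, jitter = 1, seed = 7)
  expect_identical(w1$samples, w2$samples)

  c1 <- synth_csi(w1, n_subcarriers = 16, seed = 3)
  c2 <- synth_csi(w2, n_subcarriers = 16, seed = 3)
  expect_identical(c1$magnitudes, c2$magnitudes)

  a1 <- synth_airflow(w1, seed = 5)
  a2 <- synth_airflow(w2, seed = 5)
  expect_identical(a1$pressure, a2$pressure)
})

test_that("a jitter-free constant-rate waveform is a clean 0.20 Hz tone", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  spec <- csibreath:::one_sided_spectrum(wf$samples, wf$sampling_rate)
  f_peak <- spec$freq[which.max(spec$mag)]
  expect_equal(f_peak, 0.20, tolerance = 1 / 60 / 0.2) # within one bin
  # ground truth equals the schedule everywhere when jitter = 0
  expect_equal(wf$truth$rr, rate_at(sched, wf$truth$time - 0.5))
})

test_that("rate jitter stays within its bound", {
  sched <- make_schedule(6, 3, 12, 40)
  wf <- synth_respiratory_waveform(sched, jitter = 1, seed = 2)
  expect_true(max(abs(wf$rate - rate_at(sched, wf$time))) <= 1)
})

test_that("noiseless fully-coupled CSI puts every subcarrier peak at the paced rate", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  csi <- synth_csi(wf,
    n_subcarriers = 6, coupled_fraction = 1,
    noise_scale = 0, drift_scale = 0, motion_events = 0, seed = 1
  )
  bin <- wf$sampling_rate / nrow(csi$magnitudes) # FFT bin, Hz
  for (j in seq_len(ncol(csi$magnitudes))) {
    spec <- csibreath:::one_sided_spectrum(csi$magnitudes[, j], 50)
    expect_lt(abs(spec$freq[which.max(spec$mag)] - 0.20), bin + 1e-9)
  }
})

test_that("uncoupled subcarriers have the flat-spectrum in-band energy fraction", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  fracs <- vapply(1:10, function(s) {
    csi <- synth_csi(wf,
      n_subcarriers = 4, coupled_fraction = 0,
      drift_scale = 0, motion_events = 0, seed = s
    )
    mean(apply(csi$magnitudes, 2, snr_index, sampling_rate = 50))
  }, numeric(1))
  # white noise: expected fraction = (0.583 - 0.083) / 25 = 0.02
  expect_equal(mean(fracs), 0.02, tolerance = 0.15)
})

test_that("breathing coupling adds variance over noise-only subcarriers", {
  sched <- make_schedule(12, 3, 12, 30)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  wins <- vapply(1:10, function(s) {
    coupled <- synth_csi(wf,
      n_subcarriers = 2, coupled_fraction = 1,
      motion_events = 0, seed = s
    )
    uncoupled <- synth_csi(wf,
      n_subcarriers = 2, coupled_fraction = 0,
      motion_events = 0, seed = s
    )
    mean(apply(coupled$magnitudes, 2, var)) >=
      mean(apply(uncoupled$magnitudes, 2, var))
  }, logical(1))
  expect_true(all(wins))
})

test_that("airflow round-trips through the reference pipeline", {
  sched <- make_schedule(15, 3, 15, 90)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  air <- synth_airflow(wf, noise_scale = 0, wander_scale = 0, seed = 1)
  ref <- reference_rr(air)
  expect_true(all(ref$valid))
  expect_true(all(abs(ref$rr - 15) <= 0.5))
})

test_that("a zero-amplitude waveform yields no detected breaths", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  wf$samples <- wf$samples * 0
  wf$phase <- wf$phase * 0
  air <- synth_airflow(wf, noise_scale = 0, wander_scale = 0, seed = 1)
  train <- detect_breath_peaks(
    csibreath:::new_airflow_trace(air$pressure, air$time, air$sampling_rate)
  )
  expect_length(train$peak_times, 0)
})

test_that("zero-length waveforms and bad fractions are rejected", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  bad <- wf
  bad$samples <- numeric(0)
  expect_error(synth_csi(bad, n_subcarriers = 4), "zero length")
  expect_error(synth_csi(wf, coupled_fraction = 1.5), "coupled_fraction")
  expect_error(synth_csi(wf, noise_scale = -1), "non-negative")
})

test_that("motion bursts raise the variance of the affected span", {
  sched <- make_schedule(12, 3, 12, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  csi <- synth_csi(wf,
    n_subcarriers = 4, coupled_fraction = 0, noise_scale = 0.1,
    drift_scale = 0, motion_events = 1, motion_scale = 3, seed = 4
  )
  on <- csi$metadata$motion_onsets
  burst <- wf$time >= on & wf$time < on + 3
  expect_gt(
    var(csi$magnitudes[burst, 1]),
    5 * var(csi$magnitudes[!burst, 1])
  )
})
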