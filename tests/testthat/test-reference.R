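test_that("bandpass preserves in-band tones and rejects out-of-band content", {
  tone15 <- tone_airflow(15, duration = 120)
  filt <- bandpass_airflow(tone15)
  core <- seq(1500, 2500) # away from edges
  ratio <- sd(filt$pressure[core]) / sd(tone15$pressure[core])
  expect_lt(abs(20 * log10(ratio)), 1) # within 1 dB

  tone2 <- tone_airflow(2, duration = 180)
  filt2 <- bandpass_airflow(tone2)
  core2 <- seq(2500, 3500)
  atten <- 20 * log10(sd(filt2$pressure[core2]) / sd(tone2$pressure[core2]))
  expect_lt(atten, -20)

  dc <- tone_airflow(15, duration = 60)
  dc$pressure <- dc$pressure + 5
  expect_lt(abs(mean(bandpass_airflow(dc)$pressure)), 0.05)
})

test_that("bandpass rejects invalid bands and too-short traces", {
  tone <- tone_airflow(15, duration = 60)
  expect_error(bandpass_airflow(tone, 35, 5), "band edges")
  shorty <- csibreath:::new_airflow_trace(rnorm(32), seq(0, 31) / 32, 32)
  expect_error(bandpass_airflow(shorty), "warm-up")
})

test_that("a clean tone yields one peak per breath cycle", {
  tone <- tone_airflow(15, duration = 60) # 15 cycles in 60 s
  train <- detect_breath_peaks(tone)
  expect_true(abs(length(train$peak_times) - 15) <= 1)
})

test_that("small ripples are discarded, main peaks kept", {
  fs <- 32
  tm <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * tm) + 0.1 * sin(2 * pi * 1.5 * tm)
  trace <- csibreath:::new_airflow_trace(x, tm, fs)
  train <- detect_breath_peaks(trace)
  expect_true(abs(length(train$peak_times) - 15) <= 1)
  # retained peak spacing is the breath period, not the ripple period
  expect_gt(min(diff(train$peak_times)), 2)
})

test_that("recursive discard matches the brute-force oracle", {
  fs <- 32
  for (seed in 1:8) {
    x <- withr::with_seed(seed, {
      tm <- seq(0, 30, by = 1 / fs) # <= 1000 samples
      sin(2 * pi * 0.3 * tm) + 0.25 * sin(2 * pi * 1.2 * tm + seed) +
        0.1 * rnorm(length(tm))
    })
    tm <- seq(0, 30, by = 1 / fs)
    trace <- csibreath:::new_airflow_trace(x, tm, fs)
    got <- detect_breath_peaks(trace)$peak_times
    want <- brute_force_peaks(x, tm)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("raising the discard factor never increases the peak count", {
  fs <- 32
  tm <- seq(0, 60, by = 1 / fs)
  x <- withr::with_seed(3, {
    sin(2 * pi * 0.25 * tm) + 0.3 * sin(2 * pi * 0.9 * tm) +
      0.15 * rnorm(length(tm))
  })
  trace <- csibreath:::new_airflow_trace(x, tm, fs)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), function(f) {
    length(detect_breath_peaks(trace, factor = f)$peak_times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a constant signal yields an empty peak train", {
  trace <- csibreath:::new_airflow_trace(rep(1, 200), seq_len(200) / 32, 32)
  train <- detect_breath_peaks(trace)
  expect_length(train$peak_times, 0)
})

test_that("rr_from_peaks implements (N-1)/span", {
  expect_equal(rr_from_peaks(seq(0, 28, by = 4)), (8 - 1) / 28 * 60) # 15
  expect_equal(rr_from_peaks(c(0, 15)), 4)
  expect_true(is.na(rr_from_peaks(5)))
  expect_true(is.na(rr_from_peaks(numeric(0))))
})

test_that("reference_rr recovers a constant paced rate", {
  sched <- make_schedule(12, 3, 12, 90)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  air <- synth_airflow(wf, noise_scale = 0.02, wander_scale = 0.05, seed = 1)
  ref <- reference_rr(air)
  expect_true(all(abs(ref$rr[ref$valid] - 12) <= 1))
  expect_gt(mean(ref$valid), 0.95)
})

test_that("reference_rr transitions monotonically between plateaus", {
  sched <- make_schedule(12, 3, 15, 60)
  wf <- synth_respiratory_waveform(sched, jitter = 0, seed = 1)
  air <- synth_airflow(wf, noise_scale = 0, wander_scale = 0, seed = 1)
  ref <- reference_rr(air)
  early <- ref$rr[ref$time <= 55]
  late <- ref$rr[ref$time >= 95]
  expect_true(all(abs(early - 12) <= 1))
  expect_true(all(abs(late - 15) <= 1))
  mid <- ref$rr[ref$time > 55 & ref$time < 95]
  expect_true(all(diff(mid) > -0.8)) # rising ramp, small detector wobble
})

test_that("reference_rr rejects too-short traces", {
  expect_error(reference_rr(tone_airflow(15, duration = 20)), "shorter")
})

test_that("compliance exclusion keeps <=4 brpm deviations and is idempotent", {
  sched <- make_schedule(12, 3, 12, 200)
  series <- tibble::tibble(
    time = c(50, 60, 70, 80),
    rr = c(12.5, 18, 16, NA),
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- apply_compliance_exclusion(series, sched)
  expect_equal(out$valid, c(TRUE, FALSE, TRUE, FALSE)) # 16 - 12 = 4 kept
  expect_equal(apply_compliance_exclusion(out, sched), out)
})
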