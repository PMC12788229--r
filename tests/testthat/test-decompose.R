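make_uniform_session <- function(duration, k = 2, fs = 50, fill = 1) {
  n <- duration * fs
  csibreath:::new_csi_session(
    matrix(fill, n, k), (seq_len(n) - 1) / fs,
    list(sampling_rate = fs, n_subcarriers = k, session_id = "fix")
  )
}

test_that("ingest leaves uniform sessions unchanged and flags gaps", {
  ses <- make_uniform_session(40)
  out <- ingest_csi(ses)
  expect_identical(out$magnitudes, ses$magnitudes)
  expect_equal(nrow(out$metadata$gaps), 0)

  # jittered timestamps come back on an exact 0.02 s grid
  wf <- synth_respiratory_waveform(make_schedule(12, 3, 12, 40), seed = 1)
  csi <- synth_csi(wf, n_subcarriers = 3, timestamp_jitter = TRUE, seed = 2)
  reg <- ingest_csi(csi)
  expect_equal(unique(round(diff(reg$timestamps), 9)), 0.02)

  # a 2 s gap is interpolated but flagged
  ses2 <- make_uniform_session(50)
  keep <- ses2$timestamps < 20 | ses2$timestamps > 22
  gappy <- csibreath:::new_csi_session(
    ses2$magnitudes[keep, ], ses2$timestamps[keep], ses2$metadata
  )
  out2 <- ingest_csi(gappy)
  expect_equal(nrow(out2$metadata$gaps), 1)
  expect_gt(out2$metadata$gaps$length, 1)

  expect_error(ingest_csi(make_uniform_session(29)), "30 s")
})

test_that("window counts follow the trailing-edge convention", {
  expect_equal(nrow(window_stream(make_uniform_session(1200))), 1171)
  expect_equal(nrow(window_stream(make_uniform_session(30))), 1)
  ws <- window_stream(make_uniform_session(60))
  expect_equal(ws$end_time[1], 30)
  expect_equal(ws$end_time[nrow(ws)], 60)
})

test_that("PCA projections are orthogonal and reconstruct the input", {
  x <- withr::with_seed(1, matrix(rnorm(200 * 6), 200, 6))
  set <- pca_window(x, sampling_rate = 50, n_project = 6)
  cors <- cor(set$projections)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-6)
  recon <- set$projections %*% t(set$rotation[, 1:6]) +
    matrix(set$mu, 200, 6, byrow = TRUE)
  expect_lt(max(abs(recon - x)), 1e-8)
  expect_true(all(diff(set$ratios) <= 1e-12))
  expect_lte(sum(set$ratios), 1 + 1e-9)
})

test_that("two correlated subcarriers collapse onto one component", {
  base <- tone_component(12, duration = 30)
  x <- cbind(base, 2 * base, matrix(1, length(base), 2))
  set <- pca_window(x, sampling_rate = 50)
  expect_gt(set$ratios[1], 0.999)
})

test_that("variance index finds the cumulative-variance elbow", {
  vi <- variance_index(c(0.60, 0.25, 0.10, 0.04, 0.005, 0.005))
  expect_equal(vi$m_star, 4)
  expect_equal(vi$sigma_threshold, 0.99)
  expect_equal(vi$gamma_sigma, c(1, 1, 1, 1, 0, 0))

  # floor rule: at least one component is always retained
  vi2 <- variance_index(c(0.009, rep(0.005, 5)))
  expect_equal(vi2$m_star, 1)

  # no sub-threshold increment: everything is retained
  vi3 <- variance_index(rep(0.25, 4))
  expect_equal(vi3$m_star, 4)
})

test_that("snr index measures in-band magnitude fraction", {
  expect_gt(snr_index(tone_component(18)), 0.95) # 0.3 Hz tone
  expect_lt(snr_index(tone_component(90)), 0.05) # 1.5 Hz tone
  expect_equal(snr_index(rep(0, 1500)), 0)
  fracs <- vapply(1:100, function(s) {
    snr_index(withr::with_seed(s, rnorm(1500)))
  }, numeric(1))
  expect_equal(mean(fracs), 0.02, tolerance = 0.1)
})

test_that("spectral peak index is inclusive at the physiological floor", {
  expect_equal(spectral_peak_index(tone_component(18)), 1)
  expect_equal(spectral_peak_index(tone_component(3, duration = 40)), 0)
  # 5 brpm is bin-aligned in a 24 s window: boundary peak scores 1
  expect_equal(spectral_peak_index(tone_component(5, duration = 24)), 1)
  expect_equal(spectral_peak_index(rep(0, 1500)), 0)
})

test_that("component selection ranks by CQI with variance-rank tie-break", {
  resp1 <- tone_component(17, duration = 30)
  resp2 <- tone_component(14, duration = 30)
  slow <- tone_component(1.5, duration = 30) # sub-physiological trend
  fast <- tone_component(90, duration = 30) # out-of-band
  fake <- structure(
    list(
      projections = cbind(slow, resp1, fast, slow, resp2),
      ratios = c(0.4, 0.3, 0.15, 0.1, 0.05),
      gamma_sigma = rep(1, 5), m_star = 5, sampling_rate = 50,
      degenerate = FALSE,
      scores = NULL
    ),
    class = "component_set"
  )
  sel <- select_components(fake, n_keep = 2)
  expect_equal(sort(sel$selected), c(2, 5))
  expect_false(sel$low_quality)

  # all-equal CQIs: lowest variance ranks win
  eq <- fake
  eq$projections <- cbind(resp1, resp1, resp1, resp1, resp1)
  sel2 <- select_components(eq, n_keep = 3)
  expect_equal(sel2$selected, c(1, 2, 3))

  # nothing respiratory (all peaks sub-physiological): fallback, flagged
  slow2 <- tone_component(2, duration = 30)
  none <- fake
  none$projections <- cbind(slow, slow2, slow, slow2, slow)
  sel3 <- select_components(none, n_keep = 2)
  expect_true(sel3$low_quality)
  expect_equal(sel3$selected, c(1, 2))
})

test_that("a zero-variance window degenerates gracefully", {
  x <- matrix(3, 1500, 4)
  set <- pca_window(x, sampling_rate = 50)
  expect_true(set$degenerate)
  sel <- select_components(set)
  expect_true(sel$low_quality)
  expect_true(all(sel$scores$cqi == 0))
})
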