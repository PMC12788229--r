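#' Regularise a CSI session onto a uniform packet grid
#'
#' Real packet captures have jittered inter-arrival times; all downstream
#' windowing assumes a uniform grid. Each subcarrier is linearly
#' interpolated onto an exact `1/fs` grid spanning the recording. Gaps
#' longer than one second between consecutive packets are interpolated but
#' flagged in the metadata.
#'
#' @param session A `csi_session`.
#' @param gap_threshold Gap length (seconds) above which a gap is flagged.
#' @return A `csi_session` with uniform timestamps and a `gaps` metadata
#'   entry (tibble `start`, `length`).
#' @export
ingest_csi <- function(session, gap_threshold = 1) {
  stopifnot(inherits(session, "csi_session"))
  ts <- session$timestamps
  fs <- session$metadata$sampling_rate
  if (max(ts) - min(ts) < 30) {
    stop("session shorter than 30 s cannot be analysed", call. = FALSE)
  }
  dt <- diff(ts)
  gaps <- which(dt > gap_threshold)
  gap_tbl <- tibble::tibble(start = ts[gaps], length = dt[gaps])
  grid <- seq(min(ts), max(ts), by = 1 / fs)
  uniform <- isTRUE(all.equal(ts, grid, tolerance = 1e-9)) &&
    length(ts) == length(grid)
  mags <- session$magnitudes
  if (!uniform) {
    mags <- apply(session$magnitudes, 2, function(col) {
      approx(ts, col, xout = grid, rule = 2)$y
    })
  }
  meta <- session$metadata
  meta$gaps <- gap_tbl
  new_csi_session(mags, if (uniform) ts else grid, meta)
}

#' Enumerate sliding analysis windows over a session
#'
#' Windows are `window` seconds long and advance by `step` seconds; the
#' window whose last sample falls at time `t` summarises `(t - window, t]`,
#' the trailing-edge convention shared by every module. A session of
#' duration `D` yields `floor((D - window) / step) + 1` windows.
#'
#' @param session An ingested (uniform-grid) `csi_session`.
#' @param window,step Window length and step, seconds (defaults 30 and 1).
#' @return Tibble with `window_id`, `end_time`, `start_idx`, `end_idx`.
#' @export
window_stream <- function(session, window = 30, step = 1) {
  stopifnot(inherits(session, "csi_session"))
  fs <- session$metadata$sampling_rate
  w <- round(window * fs)
  s <- round(step * fs)
  n <- nrow(session$magnitudes)
  if (n < w) stop("session shorter than one window", call. = FALSE)
  starts <- seq(1, n - w + 1, by = s)
  tibble::tibble(
    window_id = seq_along(starts),
    # rounded so 1 Hz timestamps join exactly against integer-second series
    end_time = round(session$timestamps[starts + w - 1] + 1 / fs, 6),
    start_idx = starts,
    end_idx = starts + w - 1
  )
}

# Eigendecomposition of a window from its uncentred cross-product S and
# column sums cs (n rows). Shared by pca_window() and the pipeline's
# incremental covariance update.
pca_core <- function(s_mat, cs, n) {
  k <- length(cs)
  mu <- cs / n
  cov <- (s_mat - n * tcrossprod(mu)) / (n - 1)
  eig <- eigen(cov, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  total <- sum(values)
  list(
    rotation = eig$vectors, values = values, mu = mu,
    ratios = if (total > 0) values / total else rep(0, k)
  )
}

#' Per-window principal component analysis of CSI magnitudes
#'
#' Removes each subcarrier's window mean and decomposes the W x K magnitude
#' matrix into orthogonal principal components ordered by decreasing
#' eigenvalue. The sign of each component is normalised so that its skewness
#' is non-negative (eigenvector signs are otherwise arbitrary), making the
#' projections deterministic. A zero-variance window yields a degenerate
#' single component whose quality index is forced to zero downstream.
#'
#' @param magnitudes W x K numeric matrix (one analysis window).
#' @param sampling_rate Sampling rate of the rows, Hz.
#' @param n_project Number of leading components to project (default: as
#'   many as the variance index retains, but at least `5`). `Inf` projects
#'   all.
#' @return A `component_set`: list with `projections` (W x m), `ratios`
#'   (explained-variance ratio for every component), `cumvar`, `m_star` and
#'   `sigma_threshold` from [variance_index()], `sampling_rate`, and
#'   `degenerate` flag.
#' @export
pca_window <- function(magnitudes, sampling_rate = 50, n_project = NULL) {
  stopifnot(is.matrix(magnitudes), nrow(magnitudes) > 1)
  core <- pca_core(
    crossprod(magnitudes), colSums(magnitudes), nrow(magnitudes)
  )
  build_component_set(magnitudes, core, sampling_rate, n_project)
}

build_component_set <- function(magnitudes, core, sampling_rate, n_project) {
  vi <- variance_index(core$ratios)
  degenerate <- sum(core$values) == 0
  m <- if (is.null(n_project)) max(vi$m_star, 5) else n_project
  m <- min(m, ncol(magnitudes), nrow(magnitudes) - 1)
  m <- max(m, 1)
  centred <- sweep(magnitudes, 2, core$mu)
  proj <- centred %*% core$rotation[, seq_len(m), drop = FALSE]
  # deterministic sign: non-negative skewness
  for (j in seq_len(ncol(proj))) {
    p <- proj[, j]
    sk <- mean((p - mean(p))^3)
    if (sk < 0) {
      proj[, j] <- -p
      core$rotation[, j] <- -core$rotation[, j]
    }
  }
  structure(
    list(
      projections = proj, rotation = core$rotation, mu = core$mu,
      values = core$values, ratios = core$ratios,
      cumvar = cumsum(core$ratios), m_star = vi$m_star,
      sigma_threshold = vi$sigma_threshold, gamma_sigma = vi$gamma_sigma,
      sampling_rate = sampling_rate, degenerate = degenerate
    ),
    class = "component_set"
  )
}

#' Variance index from an explained-variance spectrum
#'
#' Finds the elbow of the cumulative explained-variance curve: `m_star` is
#' the smallest rank whose *next* component would add less than
#' `gradient_threshold` (default 1%) additional variance. The variance
#' threshold is the cumulative variance retained at `m_star`. Components of
#' rank `<= m_star` receive a variance index of 1, the rest 0. At least one
#' component is always retained.
#'
#' @param ratios Per-component explained-variance ratios (non-increasing).
#' @param gradient_threshold Gradient cut-off on the cumulative curve.
#' @return List with `m_star`, `sigma_threshold`, `gamma_sigma` (0/1 vector).
#' @export
variance_index <- function(ratios, gradient_threshold = 0.01) {
  k <- length(ratios)
  below <- which(ratios < gradient_threshold)
  # smallest rank whose next component adds < threshold
  m_star <- if (length(below) == 0) k else max(below[1] - 1, 1)
  list(
    m_star = m_star,
    sigma_threshold = sum(ratios[seq_len(m_star)]),
    gamma_sigma = as.numeric(seq_len(k) <= m_star)
  )
}

one_sided_spectrum <- function(x, sampling_rate) {
  x <- x - mean(x)
  n <- length(x)
  half <- seq_len(floor(n / 2))
  list(
    freq = half * sampling_rate / n,
    mag = Mod(stats::fft(x))[half + 1]
  )
}

#' In-band spectral energy (SNR) index of a component
#'
#' Fraction of the total one-sided magnitude spectrum (mean removed, no
#' taper) that falls inside the physiological RR band. Values near 1 mean
#' nearly all spectral content is at plausible breathing frequencies.
#'
#' @param component Numeric time series.
#' @param sampling_rate Hz.
#' @param band Physiological band, brpm (default 5-35, i.e.
#'   0.083-0.583 Hz).
#' @param power Use power (`TRUE`) instead of magnitude (default `FALSE`)
#'   spectra.
#' @return Index in [0, 1]; an all-zero component returns 0.
#' @export
snr_index <- function(component, sampling_rate = 50, band = c(5, 35),
                      power = FALSE) {
  spec <- one_sided_spectrum(component, sampling_rate)
  w <- if (power) spec$mag^2 else spec$mag
  tot <- sum(w)
  if (tot == 0) {
    return(0)
  }
  fb <- brpm_to_hz(band)
  sum(w[spec$freq >= fb[1] & spec$freq <= fb[2]]) / tot
}

#' Spectral peak location index of a component
#'
#' Guards against slow 1/f-like trends that carry high variance and even
#' high in-band energy: the index is 1 only when the dominant spectral peak
#' (mean removed) lies at or above the minimum physiological rate.
#'
#' @param component Numeric time series.
#' @param sampling_rate Hz.
#' @param f_min Minimum physiological RR, brpm (default 5). The comparison
#'   is inclusive: a peak exactly at `f_min` scores 1.
#' @return 0 or 1; a flat (zero) spectrum returns 0.
#' @export
spectral_peak_index <- function(component, sampling_rate = 50, f_min = 5) {
  spec <- one_sided_spectrum(component, sampling_rate)
  if (length(spec$mag) == 0 || max(spec$mag) <= 0) {
    return(0)
  }
  f_peak <- spec$freq[which.max(spec$mag)]
  as.numeric(f_peak >= brpm_to_hz(f_min))
}

#' Score components and select the best for RR estimation
#'
#' Computes the component quality index `CQI = Gamma_sigma * Gamma_SNR *
#' Gamma_peak` for every component retained by the variance index and keeps
#' the `n_keep` components with the highest CQI (ties broken by
#' explained-variance rank). If every CQI is zero the `n_keep`
#' highest-variance components are selected instead and the set is flagged
#' `low_quality`.
#'
#' @param set A `component_set` from [pca_window()].
#' @param n_keep Number of components to keep (default 5).
#' @param band,f_min Passed to [snr_index()] and [spectral_peak_index()].
#' @param power Spectrum convention for the SNR index.
#' @return The `component_set` augmented with `scores` (tibble `rank`,
#'   `gamma_sigma`, `gamma_snr`, `gamma_peak`, `cqi`), `selected` (ranks)
#'   and `low_quality`.
#' @export
select_components <- function(set, n_keep = 5, band = c(5, 35), f_min = 5,
                              power = FALSE) {
  stopifnot(inherits(set, "component_set"), n_keep >= 1)
  m_avail <- ncol(set$projections)
  n_score <- min(max(set$m_star, n_keep), m_avail)
  fs <- set$sampling_rate
  ranks <- seq_len(n_score)
  g_sig <- if (set$degenerate) rep(0, n_score) else set$gamma_sigma[ranks]
  g_snr <- vapply(ranks, function(r) {
    snr_index(set$projections[, r], fs, band, power)
  }, numeric(1))
  g_peak <- vapply(ranks, function(r) {
    spectral_peak_index(set$projections[, r], fs, f_min)
  }, numeric(1))
  scores <- tibble::tibble(
    rank = ranks, gamma_sigma = g_sig, gamma_snr = g_snr,
    gamma_peak = g_peak, cqi = g_sig * g_snr * g_peak
  )
  low_quality <- all(scores$cqi == 0)
  ord <- order(-scores$cqi, scores$rank)
  selected <- if (low_quality) {
    seq_len(min(n_keep, m_avail))
  } else {
    head(scores$rank[ord], n_keep)
  }
  set$scores <- scores
  set$selected <- selected
  set$low_quality <- low_quality
  set
}
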