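#' Bandpass-filter a component to the physiological band
#'
#' Applies a 4th-order Butterworth high-pass at `low` and then a 4th-order
#' Butterworth low-pass at `high`, each forward-backward (zero-phase), so
#' breath-onset timestamps are preserved. Defaults bound the physiological
#' breathing range of 5-35 brpm; the narrower 6-33 brpm experimental band is
#' available as a configuration preset.
#'
#' @param component Numeric time series.
#' @param sampling_rate Hz.
#' @param band Passband edges, brpm.
#' @return Filtered, zero-mean series of the same length.
#' @export
bandpass_component <- function(component, sampling_rate = 50, band = c(5, 35)) {
  stopifnot(band[1] > 0, band[1] < band[2])
  fs <- sampling_rate
  if (length(component) < 4 * fs) {
    stop("component shorter than the filter warm-up", call. = FALSE)
  }
  hp <- signal::butter(4, brpm_to_hz(band[1]) / (fs / 2), type = "high")
  lp <- signal::butter(4, brpm_to_hz(band[2]) / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, component - mean(component)))
}

#' Breath-onset detection by the box slope sum function
#'
#' Transforms a filtered, zero-mean component into a slope-sum signal -- a
#' sliding box sum of the positive first differences -- whose rises mark
#' breath onsets. Onsets are taken at upward crossings of an adaptive
#' threshold (a fraction of the median height of the slope-sum local
#' maxima in the window), searched back to the start of the rise, and a
#' refractory period of `60 / f_max` seconds suppresses spurious re-triggers
#' within one minimal breath period.
#'
#' @param filtered Zero-mean numeric series (see [bandpass_component()]).
#' @param sampling_rate Hz.
#' @param box Box width of the slope sum, seconds (default 1).
#' @param f_max Fastest physiological RR, brpm; sets the refractory period.
#' @param threshold_frac Threshold as a fraction of the median slope-sum
#'   peak height (default 0.5).
#' @return An `onset_train`: list with `onset_times` (seconds, strictly
#'   increasing, spaced by at least the refractory period). All-zero input
#'   yields an empty train.
#' @export
bssf_onsets <- function(filtered, sampling_rate = 50, box = 1, f_max = 35,
                        threshold_frac = 0.5) {
  n <- length(filtered)
  w <- max(round(box * sampling_rate), 1)
  d <- pmax(diff(filtered), 0)
  cs <- cumsum(c(0, d))
  idx <- seq_len(n - 1)
  ssf <- cs[idx + 1] - cs[pmax(idx + 1 - w, 1)]
  ext <- find_extrema(ssf)
  heights <- ext$value[ext$type == "peak"]
  if (length(heights) == 0 || max(ssf) <= 0) {
    return(new_onset_train(numeric(0)))
  }
  thr <- threshold_frac * median(heights)
  if (thr <= 0) {
    return(new_onset_train(numeric(0)))
  }
  above <- ssf >= thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  refractory <- 60 / f_max
  onsets <- numeric(0)
  last <- -Inf
  for (cx in crossings) {
    # search back to the start of the slope-sum rise
    j <- cx
    while (j > 1 && ssf[j - 1] < ssf[j] && ssf[j - 1] > 0.01 * thr) j <- j - 1
    t_on <- (j - 1) / sampling_rate
    if (t_on - last >= refractory) {
      onsets <- c(onsets, t_on)
      last <- t_on
    }
  }
  new_onset_train(onsets)
}

new_onset_train <- function(onset_times) {
  stopifnot(!is.unsorted(onset_times, strictly = TRUE))
  structure(list(onset_times = onset_times), class = "onset_train")
}

#' RR from breath onsets (time-domain estimator)
#'
#' `RR = (N_onsets - 1) / (t_final - t_start) * 60`. Fewer than two onsets
#' give `NA` (invalid candidate).
#'
#' @param train An `onset_train` or numeric vector of onset times, seconds.
#' @return RR in brpm, or `NA_real_`.
#' @export
rr_breath <- function(train) {
  ot <- if (inherits(train, "onset_train")) train$onset_times else train
  if (length(ot) < 2) {
    return(NA_real_)
  }
  span <- max(ot) - min(ot)
  if (span <= 0) {
    return(NA_real_)
  }
  (length(ot) - 1) / span * 60
}

#' RR from the dominant spectral peak (frequency-domain estimator)
#'
#' Applies a Hann taper, computes the FFT, and returns 60 times the
#' frequency of the largest spectral magnitude inside the physiological
#' band. The frequency resolution is `1/T` Hz: 0.033 Hz (2 brpm) for the
#' default 30 s window, which lower-bounds the achievable accuracy.
#'
#' @param filtered Numeric series (one analysis window).
#' @param sampling_rate Hz.
#' @param band Search band, brpm.
#' @return RR in brpm, or `NA_real_` when no in-band bin rises above the
#'   spectral floor (e.g. a constant signal).
#' @export
rr_fft <- function(filtered, sampling_rate = 50, band = c(5, 35)) {
  n <- length(filtered)
  x <- filtered - mean(filtered)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  spec <- one_sided_spectrum(x * hann, sampling_rate)
  fb <- brpm_to_hz(band)
  in_band <- spec$freq >= fb[1] & spec$freq <= fb[2]
  if (!any(in_band)) {
    return(NA_real_)
  }
  floor_level <- 1e-10 * n * max(1e-300, stats::sd(x))
  mags <- spec$mag[in_band]
  if (max(mags) <= floor_level || max(mags) == 0) {
    return(NA_real_)
  }
  60 * spec$freq[in_band][which.max(mags)]
}

#' Combine the two per-component RR estimates
#'
#' The combined estimate is the arithmetic mean of the breath-counting and
#' spectral-peak values when both are defined. If exactly one is defined it
#' is returned as-is but the agreement factor must be forced to 0 by the
#' caller (a conservative quality penalty); if neither is defined the
#' candidate is invalid.
#'
#' @param rr_breath,rr_fft RR estimates, brpm (either may be `NA`).
#' @return Combined RR in brpm, or `NA_real_`.
#' @export
rr_combined <- function(rr_breath, rr_fft) {
  if (is.na(rr_breath) && is.na(rr_fft)) {
    return(NA_real_)
  }
  if (is.na(rr_breath)) {
    return(rr_fft)
  }
  if (is.na(rr_fft)) {
    return(rr_breath)
  }
  (rr_breath + rr_fft) / 2
}

#' Estimation agreement factor
#'
#' 1 when the spectral and breath-count estimates agree within `tolerance`
#' brpm (boundary inclusive), 0 otherwise or when either is undefined.
#'
#' @param rr_fft,rr_breath RR estimates, brpm.
#' @param tolerance Agreement tolerance, brpm (default 4).
#' @return 0 or 1.
#' @export
agreement_factor <- function(rr_fft, rr_breath, tolerance = 4) {
  stopifnot(tolerance > 0)
  if (is.na(rr_fft) || is.na(rr_breath)) {
    return(0)
  }
  as.numeric(abs(rr_fft - rr_breath) <= tolerance)
}

# One-sided power-spectral moments with frequency normalised to
# radians/sample on [0, pi]. When `f_cap` (Hz) is supplied, the moments are
# restricted to bins at or below it and omega is rescaled so the capped
# range maps to [0, pi] -- equivalent to ideal decimation to 2 * f_cap.
spectral_moments <- function(x, orders = c(0, 2, 4), sampling_rate = NULL,
                             f_cap = NULL) {
  x <- x - mean(x)
  n <- length(x)
  half <- 0:floor(n / 2)
  p <- Mod(stats::fft(x))[half + 1]^2
  omega <- 2 * pi * half / n
  if (!is.null(f_cap)) {
    stopifnot(!is.null(sampling_rate), f_cap > 0, f_cap <= sampling_rate / 2)
    freq <- half * sampling_rate / n
    keep <- freq <= f_cap
    p <- p[keep]
    omega <- pi * freq[keep] / f_cap
  }
  vapply(orders, function(k) sum(omega^k * p), numeric(1))
}

#' Spectral purity index
#'
#' `SPI = m2^2 / (m0 * m4)` where `m_n` is the nth-order moment of the
#' one-sided power spectrum with frequency in radians per sample. By the
#' Cauchy-Schwarz inequality the index lies in [0, 1]; it equals 1 for a
#' single dominant tone and takes the closed-form value 5/9 for a perfectly
#' flat spectrum. Zero-power input returns 0.
#'
#' When the band of interest sits far below the Nyquist frequency (a 0.1 Hz
#' breath in a 50 Hz recording), the fourth moment is dominated by whatever
#' residual power sits near Nyquist and the index loses discrimination.
#' Supplying `f_cap` restricts the moments to the spectrum at or below that
#' frequency and rescales omega so the capped range spans [0, pi] --
#' exactly the index an ideal decimation to `2 * f_cap` Hz would give. The
#' pipeline uses `f_cap` at twice the upper band edge.
#'
#' @param filtered Numeric time series.
#' @param sampling_rate Hz; only needed with `f_cap`.
#' @param f_cap Optional moment cap, Hz.
#' @return SPI in [0, 1].
#' @export
spectral_purity <- function(filtered, sampling_rate = NULL, f_cap = NULL) {
  m <- spectral_moments(filtered, sampling_rate = sampling_rate, f_cap = f_cap)
  if (m[1] <= 0 || m[3] <= 0) {
    return(0)
  }
  m[2]^2 / (m[1] * m[3])
}

#' Candidate signal quality index
#'
#' `SQI = Gamma_SNR * Gamma_agree * Gamma_SPI`: the product of the in-band
#' energy fraction of the *unfiltered* component, the estimator agreement
#' factor, and the spectral purity of the filtered component. Any factor of
#' zero annihilates the index.
#'
#' @param gamma_snr,gamma_agree,gamma_spi The three factors, each in [0, 1].
#' @return SQI in [0, 1].
#' @export
candidate_sqi <- function(gamma_snr, gamma_agree, gamma_spi) {
  stopifnot(
    gamma_snr >= 0, gamma_snr <= 1, gamma_agree %in% c(0, 1),
    gamma_spi >= 0, gamma_spi <= 1
  )
  gamma_snr * gamma_agree * gamma_spi
}

#' Estimate RR candidates for the selected components of one window
#'
#' For each selected component: bandpass to the physiological band,
#' breath-count via the slope-sum onset detector, locate the dominant
#' spectral peak, combine the two estimates, and attach the signal quality
#' index. The SNR factor of the SQI is the component's in-band energy
#' fraction computed *before* filtering (filtering would trivially inflate
#' it).
#'
#' @param set A `component_set` from [select_components()].
#' @param band Filter/search band, brpm.
#' @param tolerance Agreement tolerance, brpm.
#' @param bssf List of slope-sum parameters: `box` (s), `threshold_frac`,
#'   `f_max` (brpm, defaults to the band's upper edge).
#' @return Tibble with one row per selected component: `rank`, `rr_breath`,
#'   `rr_fft`, `rr_combined`, `gamma_snr`, `gamma_agree`, `gamma_spi`,
#'   `sqi`, `valid`.
#' @export
estimate_components <- function(set, band = c(5, 35), tolerance = 4,
                                bssf = list()) {
  stopifnot(inherits(set, "component_set"), !is.null(set$selected))
  fs <- set$sampling_rate
  box <- bssf$box %||% 1
  thr <- bssf$threshold_frac %||% 0.5
  f_max <- bssf$f_max %||% band[2]
  f_cap <- 2 * brpm_to_hz(band[2])
  nsel <- length(set$selected)
  rb <- rf <- rc <- g_snr <- g_agree <- g_spi <- numeric(nsel)
  for (i in seq_len(nsel)) {
    r <- set$selected[i]
    raw <- set$projections[, r]
    g_snr[i] <- if (r <= nrow(set$scores)) {
      set$scores$gamma_snr[set$scores$rank == r]
    } else {
      snr_index(raw, fs, band)
    }
    filt <- bandpass_component(raw, fs, band)
    rb[i] <- rr_breath(bssf_onsets(filt, fs, box, f_max, thr))
    rf[i] <- rr_fft(filt, fs, band)
    rc[i] <- rr_combined(rb[i], rf[i])
    g_agree[i] <- agreement_factor(rf[i], rb[i], tolerance)
    g_spi[i] <- spectral_purity(filt, fs, f_cap)
  }
  tibble::tibble(
    rank = set$selected, rr_breath = rb, rr_fft = rf, rr_combined = rc,
    gamma_snr = g_snr, gamma_agree = g_agree, gamma_spi = g_spi,
    sqi = g_snr * g_agree * g_spi, valid = !is.na(rc)
  )
}
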