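#' Bandpass-filter an airflow trace to the physiological breathing band
#'
#' Applies an 8th-order Butterworth IIR bandpass (two 4th-order halves in
#' the digital design) between `low` and `high` brpm, forward-backward so
#' the result is zero-phase and breath-peak timestamps are not skewed.
#' Note the two-pass application doubles the effective stopband attenuation.
#'
#' @param trace An `airflow_trace`.
#' @param low,high Passband edges, brpm (defaults 5-35).
#' @return A filtered `airflow_trace` of the same length.
#' @export
bandpass_airflow <- function(trace, low = 5, high = 35) {
  stopifnot(inherits(trace, "airflow_trace"))
  fs <- trace$sampling_rate
  if (!(low > 0 && low < high && brpm_to_hz(high) < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  if (length(trace$pressure) < 8 * fs) {
    stop("trace too short for the filter warm-up", call. = FALSE)
  }
  bp <- signal::butter(4, brpm_to_hz(c(low, high)) / (fs / 2), type = "pass")
  new_airflow_trace(
    signal::filtfilt(bp, trace$pressure - mean(trace$pressure)),
    trace$time, fs
  )
}

#' Detect breath peaks with a quartile-thresholded recursive discard
#'
#' Implements the classical breath-detection scheme for airflow signals:
#' all alternating local maxima and minima are located, the absolute vertical
#' differences between adjacent extrema are collected and their third
#' quartile Q3 computed, then peaks whose vertical separation from the
#' nearest trough is below `factor * Q3` are discarded recursively. After
#' each removal the two troughs flanking the removed peak are merged (the
#' deeper one is kept) and separations are re-evaluated, until a full pass
#' removes nothing. Discarding strictly reduces the peak count, so
#' termination is guaranteed.
#'
#' @param filtered An `airflow_trace` (normally the output of
#'   [bandpass_airflow()]), or any zero-mean numeric signal wrapped in one.
#' @param factor Fraction of Q3 used as the discard threshold (default 0.3).
#' @return A `peak_train`: list with `peak_times`, `trough_times` (seconds),
#'   and `q3` (the quartile used). A constant or too-short signal yields an
#'   empty train, not an error.
#' @export
detect_breath_peaks <- function(filtered, factor = 0.3) {
  stopifnot(inherits(filtered, "airflow_trace"))
  ext <- find_extrema(filtered$pressure)
  if (nrow(ext) < 2) {
    return(new_peak_train(numeric(0), numeric(0), NA_real_))
  }
  q3 <- unname(quantile(abs(diff(ext$value)), 0.75))
  thr <- factor * q3
  repeat {
    peaks <- which(ext$type == "peak")
    if (length(peaks) == 0) break
    # vertical separation of each peak from its nearest adjacent trough
    sep <- vapply(peaks, function(p) {
      nb <- c(
        if (p > 1) abs(ext$value[p] - ext$value[p - 1]),
        if (p < nrow(ext)) abs(ext$value[p] - ext$value[p + 1])
      )
      min(nb)
    }, numeric(1))
    bad <- peaks[sep < thr]
    if (length(bad) == 0) break
    # remove the worst offender, then merge its flanking troughs
    drop <- bad[which.min(sep[match(bad, peaks)])]
    lo <- if (drop > 1) drop - 1 else NA
    hi <- if (drop < nrow(ext)) drop + 1 else NA
    remove <- drop
    if (!is.na(lo) && !is.na(hi)) {
      # keep the deeper trough
      remove <- c(remove, if (ext$value[lo] <= ext$value[hi]) hi else lo)
    }
    ext <- ext[-remove, , drop = FALSE]
  }
  new_peak_train(
    filtered$time[ext$idx[ext$type == "peak"]],
    filtered$time[ext$idx[ext$type == "trough"]],
    q3
  )
}

new_peak_train <- function(peak_times, trough_times, q3) {
  structure(
    list(peak_times = peak_times, trough_times = trough_times, q3 = q3),
    class = "peak_train"
  )
}

#' Respiratory rate from a train of breath peaks
#'
#' `RR = (N - 1) / (t_last - t_first) * 60`, i.e. the number of complete
#' breath-to-breath intervals divided by the time they span. Fewer than two
#' peaks give `NA` (the window is invalid, not an error).
#'
#' @param train A `peak_train`, or a numeric vector of peak times in seconds.
#' @return RR in brpm, or `NA_real_`.
#' @export
rr_from_peaks <- function(train) {
  pt <- if (inherits(train, "peak_train")) train$peak_times else train
  if (length(pt) < 2) {
    return(NA_real_)
  }
  span <- max(pt) - min(pt)
  if (span <= 0) {
    return(NA_real_)
  }
  (length(pt) - 1) / span * 60
}

#' Reference RR series from an airflow trace
#'
#' Bandpass-filters the trace, then slides a `window`-second window in
#' `step`-second steps. In each window breath peaks are detected with the
#' per-window quartile threshold of [detect_breath_peaks()] and the RR is
#' computed from the peak train. The estimate timestamped `t` summarises the
#' interval `(t - window, t]`. Windows with fewer than two peaks, or an RR
#' outside [0, 60] brpm, are flagged invalid and never interpolated.
#'
#' @param trace An `airflow_trace`.
#' @param window Window length, seconds (default 30).
#' @param step Step between estimates, seconds (default 1, i.e. a 1 Hz
#'   output series).
#' @param band Bandpass edges in brpm passed to [bandpass_airflow()].
#' @return A tibble of class `rr_series` with columns `time`, `rr`, `valid`.
#' @export
reference_rr <- function(trace, window = 30, step = 1, band = c(5, 35)) {
  stopifnot(inherits(trace, "airflow_trace"))
  dur <- max(trace$time) - min(trace$time)
  if (dur < window) stop("trace shorter than one window", call. = FALSE)
  filt <- bandpass_airflow(trace, band[1], band[2])
  ends <- seq(min(trace$time) + window, max(trace$time), by = step)
  rr <- vapply(ends, function(te) {
    in_win <- filt$time > te - window & filt$time <= te
    seg <- new_airflow_trace(
      filt$pressure[in_win], filt$time[in_win], filt$sampling_rate
    )
    rr_from_peaks(detect_breath_peaks(seg))
  }, numeric(1))
  valid <- !is.na(rr) & rr >= 0 & rr <= 60
  out <- tibble::tibble(time = ends, rr = rr, valid = valid)
  class(out) <- c("rr_series", class(out))
  out
}

#' Flag windows where the subject did not follow the metronome
#'
#' Marks estimates invalid where the absolute difference between the
#' reference RR and the paced rate at that time is *strictly greater* than
#' `tolerance` brpm (a difference of exactly `tolerance` is kept). Existing
#' invalid flags are preserved; the operation is idempotent.
#'
#' @param series An `rr_series` tibble (`time`, `rr`, `valid`).
#' @param schedule A [make_schedule()] object.
#' @param tolerance Compliance tolerance, brpm (default 4).
#' @return The series with updated `valid` flags.
#' @export
apply_compliance_exclusion <- function(series, schedule, tolerance = 4) {
  stopifnot(tolerance > 0)
  dev <- abs(series$rr - rate_at(schedule, series$time))
  series$valid <- series$valid & !is.na(dev) & dev <= tolerance
  series
}
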