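#' @importFrom stats rnorm runif rlnorm approx quantile median sd var cor
#' @importFrom utils head tail
NULL

# Raised-cosine breath cycle: u in [0, 1) is the position within the cycle,
# `asymmetry` the fraction spent inhaling. Returns displacement in [0, 1].
breath_shape <- function(u, asymmetry = 0.4) {
  stopifnot(asymmetry > 0, asymmetry < 1)
  ifelse(
    u < asymmetry,
    0.5 * (1 - cos(pi * u / asymmetry)),
    0.5 * (1 + cos(pi * (u - asymmetry) / (1 - asymmetry)))
  )
}

#' Synthesise a paced respiratory displacement waveform
#'
#' Generates a phase-continuous, quasi-periodic chest-displacement signal
#' whose instantaneous rate follows a metronome schedule with a bounded
#' random-walk deviation ("jitter", emulating imperfect metronome
#' compliance). Breath cycles are raised cosines with an inhale/exhale
#' asymmetry, so the waveform carries harmonics like a real nasal-pressure
#' or chest signal rather than being a pure sinusoid.
#'
#' @param schedule A [make_schedule()] object.
#' @param sampling_rate Output sampling rate, Hz. Must exceed twice the
#'   fastest scheduled rate (in Hz).
#' @param jitter Maximum deviation of the instantaneous rate from the paced
#'   rate, brpm. `0` gives exact compliance.
#' @param asymmetry Fraction of each cycle spent inhaling, in (0, 1).
#'   `0.5` gives a pure sinusoid.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A `respiratory_waveform`: list with `samples` (displacement,
#'   centred, peak-to-peak 1), `time`, `sampling_rate`, `rate` (per-sample
#'   instantaneous rate, brpm), `truth` (tibble `time`, `rr`: 1 Hz ground
#'   truth, each value the mean rate over the preceding second), `schedule`.
#' @export
synth_respiratory_waveform <- function(schedule, sampling_rate = 50,
                                       jitter = 0.5, asymmetry = 0.4,
                                       seed = 1) {
  stopifnot(inherits(schedule, "metronome_schedule"))
  if (sampling_rate <= 2 * schedule$end / 60) {
    stop("`sampling_rate` must exceed twice the fastest scheduled rate",
      call. = FALSE
    )
  }
  n <- round(schedule$duration * sampling_rate)
  tm <- (seq_len(n) - 1) / sampling_rate
  paced <- rate_at(schedule, tm)
  dev <- numeric(n)
  if (jitter > 0) {
    dev <- withr::with_seed(seed, {
      steps <- rnorm(n, sd = jitter * 0.02)
      d <- numeric(n)
      for (i in 2:n) d[i] <- min(max(d[i - 1] + steps[i], -jitter), jitter)
      d
    })
  }
  rate <- paced + dev
  phase <- cumsum(rate / 60) / sampling_rate # cycles
  u <- phase %% 1
  samples <- breath_shape(u, asymmetry) - 0.5
  truth_time <- seq_len(floor(schedule$duration))
  truth_rr <- vapply(truth_time, function(tt) {
    idx <- which(tm > tt - 1 & tm <= tt)
    mean(rate[idx])
  }, numeric(1))
  structure(
    list(
      samples = samples, time = tm, sampling_rate = sampling_rate,
      rate = rate, phase = phase,
      truth = tibble::tibble(time = truth_time, rr = truth_rr),
      schedule = schedule, jitter = jitter, asymmetry = asymmetry, seed = seed
    ),
    class = "respiratory_waveform"
  )
}

# Slow baseline wander: white noise low-passed below `cutoff` Hz, scaled to
# a target standard deviation. Generated at 1 Hz and interpolated, which is
# exact enough for sub-0.05 Hz content and much cheaper than filtering at
# the full rate.
slow_drift <- function(time, scale, cutoff = 0.05) {
  if (scale <= 0) {
    return(numeric(length(time)))
  }
  dur <- ceiling(max(time)) + 2
  w <- cumsum(rnorm(dur))
  lp <- signal::butter(2, cutoff / 0.5, "low")
  d <- signal::filtfilt(lp, w - mean(w))
  s <- sd(d)
  if (s > 0) d <- d / s * scale
  approx(seq_len(dur) - 1, d, xout = time, rule = 2)$y
}

#' Synthesise a CSI magnitude session
#'
#' Builds a T x K matrix of per-packet Wi-Fi subcarrier magnitudes in which a
#' random subject-dependent subset of subcarriers is modulated by a
#' respiratory displacement waveform. Each coupled subcarrier receives the
#' waveform with its own log-normally distributed gain and a random phase lag
#' of up to one breath period, on top of a per-subcarrier baseline level,
#' slow 1/f-like drift and white noise. Uncoupled subcarriers carry drift and
#' noise only. Optional motion artefacts inject short rectangular bursts of
#' high-variance noise across all subcarriers.
#'
#' @param waveform A [synth_respiratory_waveform()] object.
#' @param n_subcarriers Number of subcarriers K (default 256, an 80 MHz
#'   OFDM channel).
#' @param coupled_fraction Fraction of subcarriers modulated by breathing,
#'   in (0, 1].  `0` is allowed and yields a breathing-free session.
#' @param modulation_depth Median oscillation gain of a coupled subcarrier
#'   (magnitude units per unit displacement).
#' @param drift_scale Standard deviation of the slow baseline drift.
#' @param noise_scale Standard deviation of the additive white noise.
#' @param motion_events Number of transient motion bursts.
#' @param motion_duration Duration of each burst, seconds.
#' @param motion_scale Standard deviation of burst noise (all subcarriers).
#' @param timestamp_jitter If `TRUE`, perturb packet timestamps by up to
#'   +/-20% of the nominal spacing (ingest regularises them back).
#' @param seed Integer seed.
#' @return A `csi_session`: list with `magnitudes` (T x K, non-negative),
#'   `timestamps` (seconds), and `metadata` (sampling rate, subcarrier count,
#'   session id, seed, schedule, coupled subcarrier indices, motion onsets,
#'   and the 1 Hz ground-truth RR tibble).
#' @export
synth_csi <- function(waveform, n_subcarriers = 256, coupled_fraction = 0.2,
                      modulation_depth = 0.5, drift_scale = 0.3,
                      noise_scale = 0.25, motion_events = 2,
                      motion_duration = 3, motion_scale = 2,
                      timestamp_jitter = FALSE, seed = 1) {
  stopifnot(inherits(waveform, "respiratory_waveform"))
  if (coupled_fraction < 0 || coupled_fraction > 1) {
    stop("`coupled_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_scale < 0 || drift_scale < 0) {
    stop("noise and drift scales must be non-negative", call. = FALSE)
  }
  n <- length(waveform$samples)
  if (n == 0) stop("waveform has zero length", call. = FALSE)
  k <- n_subcarriers
  fs <- waveform$sampling_rate
  withr::with_seed(seed, {
    n_coupled <- round(coupled_fraction * k)
    coupled <- sort(sample.int(k, n_coupled))
    baseline <- rlnorm(k, log(20), 0.2)
    mags <- matrix(rnorm(n * k, sd = noise_scale), n, k)
    mags <- sweep(mags, 2, baseline, "+")
    if (drift_scale > 0) {
      for (j in seq_len(k)) {
        mags[, j] <- mags[, j] + slow_drift(waveform$time, drift_scale)
      }
    }
    if (n_coupled > 0) {
      gains <- modulation_depth * rlnorm(n_coupled, 0, 0.5)
      # per-subcarrier phase lag, uniform over one breath cycle
      lags <- runif(n_coupled)
      for (i in seq_len(n_coupled)) {
        w <- breath_shape(
          (waveform$phase + lags[i]) %% 1, waveform$asymmetry
        ) - 0.5
        mags[, coupled[i]] <- mags[, coupled[i]] + gains[i] * w
      }
    }
    motion_onsets <- numeric(0)
    if (motion_events > 0) {
      motion_onsets <- sort(runif(
        motion_events, 0,
        max(waveform$time) - motion_duration
      ))
      for (on in motion_onsets) {
        rows <- which(waveform$time >= on & waveform$time < on + motion_duration)
        mags[rows, ] <- mags[rows, ] +
          matrix(rnorm(length(rows) * k, sd = motion_scale), length(rows), k)
      }
    }
    timestamps <- waveform$time
    if (timestamp_jitter) {
      dt <- 1 / fs
      timestamps <- timestamps + runif(n, -0.2 * dt, 0.2 * dt)
      timestamps[1] <- max(timestamps[1], 0)
    }
    mags <- pmax(mags, 0)
    new_csi_session(
      magnitudes = mags, timestamps = timestamps,
      metadata = list(
        sampling_rate = fs, n_subcarriers = k,
        session_id = sprintf("synthetic-%d", seed), seed = seed,
        schedule = waveform$schedule, coupled_subcarriers = coupled,
        motion_onsets = motion_onsets, ground_truth = waveform$truth
      )
    )
  })
}

new_csi_session <- function(magnitudes, timestamps, metadata) {
  stopifnot(
    is.matrix(magnitudes), nrow(magnitudes) == length(timestamps),
    all(is.finite(magnitudes)), all(magnitudes >= 0),
    !is.unsorted(timestamps)
  )
  structure(
    list(magnitudes = magnitudes, timestamps = timestamps, metadata = metadata),
    class = "csi_session"
  )
}

#' @export
print.csi_session <- function(x, ...) {
  cat(sprintf(
    "<csi_session> %d packets x %d subcarriers, %.1f s at %g Hz (%s)\n",
    nrow(x$magnitudes), ncol(x$magnitudes),
    diff(range(x$timestamps)), x$metadata$sampling_rate,
    x$metadata$session_id %||% "unnamed"
  ))
  invisible(x)
}

#' Synthesise a nasal-airflow pressure trace
#'
#' Emulates a nasal-cannula pressure signal phase-locked to a respiratory
#' displacement waveform. Nasal pressure tracks airflow, i.e. the rate of
#' change of lung volume, so the trace is the (scaled) time derivative of the
#' displacement, plus additive white noise and slow baseline wander, sampled
#' at 32 Hz.
#'
#' @param waveform A [synth_respiratory_waveform()] object.
#' @param noise_scale Standard deviation of additive noise (signal has unit
#'   peak amplitude).
#' @param wander_scale Standard deviation of sub-0.05 Hz baseline wander.
#' @param sampling_rate Output rate, Hz.
#' @param seed Integer seed.
#' @return An `airflow_trace`: list with `pressure`, `time`, `sampling_rate`.
#' @export
synth_airflow <- function(waveform, noise_scale = 0.05, wander_scale = 0.1,
                          sampling_rate = 32, seed = 1) {
  stopifnot(inherits(waveform, "respiratory_waveform"))
  dur <- max(waveform$time)
  tm <- seq(0, dur, by = 1 / sampling_rate)
  disp <- approx(waveform$time, waveform$samples, xout = tm, rule = 2)$y
  flow <- c(0, diff(disp)) * sampling_rate
  pk <- max(abs(flow))
  if (pk > 0) flow <- flow / pk
  withr::with_seed(seed, {
    pressure <- flow +
      rnorm(length(tm), sd = noise_scale) +
      slow_drift(tm, wander_scale)
    new_airflow_trace(pressure, tm, sampling_rate)
  })
}

new_airflow_trace <- function(pressure, time, sampling_rate) {
  stopifnot(all(is.finite(pressure)), sampling_rate > 0)
  structure(
    list(pressure = pressure, time = time, sampling_rate = sampling_rate),
    class = "airflow_trace"
  )
}

#' @export
print.airflow_trace <- function(x, ...) {
  cat(sprintf(
    "<airflow_trace> %d samples, %.1f s at %g Hz\n",
    length(x$pressure), diff(range(x$time)), x$sampling_rate
  ))
  invisible(x)
}

#' Noise profile presets for the session generator
#'
#' Named parameter bundles for [synth_session()]: `clean` (half the
#' subcarriers strongly coupled, negligible noise, no motion), `moderate`
#' (one fifth coupled with mid-level gain, drift, noise and two motion
#' bursts -- the package's default study condition) and `noisy` (sparser
#' coupling, weaker gain, heavier noise and four bursts).
#'
#' @param name One of `"clean"`, `"moderate"`, `"noisy"`.
#' @return Named list of [synth_csi()] arguments.
#' @export
synth_profile <- function(name = c("moderate", "clean", "noisy")) {
  name <- match.arg(name)
  switch(name,
    clean = list(
      coupled_fraction = 0.5, modulation_depth = 1, drift_scale = 0,
      noise_scale = 0.05, motion_events = 0
    ),
    moderate = list(
      coupled_fraction = 0.2, modulation_depth = 0.5, drift_scale = 0.3,
      noise_scale = 0.25, motion_events = 2
    ),
    noisy = list(
      coupled_fraction = 0.1, modulation_depth = 0.3, drift_scale = 0.6,
      noise_scale = 0.6, motion_events = 4
    )
  )
}

#' Generate a complete synthetic recording session
#'
#' Convenience wrapper producing a matched triple (respiratory waveform, CSI
#' session, airflow trace) from one schedule, profile and seed.
#'
#' @param schedule A [make_schedule()] object.
#' @param profile Profile name, see [synth_profile()].
#' @param seed Integer seed shared by all three generators.
#' @param jitter Metronome-compliance jitter passed to the waveform, brpm.
#' @param n_subcarriers Subcarrier count K.
#' @return List with elements `waveform`, `csi`, `airflow`.
#' @export
synth_session <- function(schedule = make_schedule(), profile = "moderate",
                          seed = 1, jitter = 0.5, n_subcarriers = 256) {
  pars <- synth_profile(profile)
  wf <- synth_respiratory_waveform(schedule, jitter = jitter, seed = seed)
  csi <- do.call(synth_csi, c(
    list(waveform = wf, n_subcarriers = n_subcarriers, seed = seed), pars
  ))
  air <- synth_airflow(wf, seed = seed)
  list(waveform = wf, csi = csi, airflow = air)
}
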