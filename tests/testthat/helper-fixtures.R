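# Shared fixtures, built in code at test time.

# sinusoidal "airflow" trace: rate in brpm
tone_airflow <- function(rate_brpm, duration = 60, fs = 32, amplitude = 1,
                         noise = 0, seed = 1) {
  tm <- seq(0, duration, by = 1 / fs)
  x <- amplitude * sin(2 * pi * rate_brpm / 60 * tm)
  if (noise > 0) x <- x + withr::with_seed(seed, rnorm(length(tm), sd = noise))
  csibreath:::new_airflow_trace(x, tm, fs)
}

# sinusoidal component at `rate_brpm`, default one 30 s analysis window
tone_component <- function(rate_brpm, duration = 30, fs = 50, amplitude = 1,
                           noise = 0, seed = 1) {
  tm <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amplitude * sin(2 * pi * rate_brpm / 60 * tm)
  if (noise > 0) x <- x + withr::with_seed(seed, rnorm(length(tm), sd = noise))
  x
}

# signal whose one-sided magnitude spectrum is exactly flat
flat_spectrum_signal <- function(n = 1001, seed = 1) {
  stopifnot(n %% 2 == 1)
  half <- (n - 1) / 2
  phases <- withr::with_seed(seed, runif(half, 0, 2 * pi))
  spec <- complex(modulus = c(0, rep(1, half)), argument = c(0, phases))
  spec <- c(spec, Conj(rev(spec[-1])))
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# Independent brute-force reference for the quartile-threshold peak
# discard: each pass rebuilds the full alternating extrema sequence from
# the surviving sample indices and re-evaluates every peak-trough pairing.
brute_force_peaks <- function(x, time, factor = 0.3) {
  ext <- csibreath:::find_extrema(x)
  if (nrow(ext) < 2) {
    return(numeric(0))
  }
  q3 <- unname(quantile(abs(diff(ext$value)), 0.75))
  thr <- factor * q3
  keep <- rep(TRUE, nrow(ext))
  repeat {
    cur <- ext[keep, , drop = FALSE]
    # enforce alternation: collapse runs of equal type, keeping the extreme one
    i <- 1
    sel <- logical(nrow(cur))
    while (i <= nrow(cur)) {
      j <- i
      while (j < nrow(cur) && cur$type[j + 1] == cur$type[i]) j <- j + 1
      run <- i:j
      best <- if (cur$type[i] == "peak") {
        run[which.max(cur$value[run])]
      } else {
        run[which.min(cur$value[run])]
      }
      sel[best] <- TRUE
      i <- j + 1
    }
    cur <- cur[sel, , drop = FALSE]
    peaks <- which(cur$type == "peak")
    if (length(peaks) == 0) break
    sep <- vapply(peaks, function(p) {
      nb <- c(
        if (p > 1) abs(cur$value[p] - cur$value[p - 1]),
        if (p < nrow(cur)) abs(cur$value[p] - cur$value[p + 1])
      )
      min(nb)
    }, numeric(1))
    if (all(sep >= thr)) {
      keep <- rep(FALSE, nrow(ext))
      keep[match(cur$idx, ext$idx)] <- TRUE
      break
    }
    worst <- peaks[which.min(sep)]
    drop_idx <- cur$idx[worst]
    # also drop the shallower flanking trough so alternation can re-form
    lo <- if (worst > 1) worst - 1 else NA
    hi <- if (worst < nrow(cur)) worst + 1 else NA
    if (!is.na(lo) && !is.na(hi)) {
      shallower <- if (cur$value[lo] <= cur$value[hi]) hi else lo
      drop_idx <- c(drop_idx, cur$idx[shallower])
    }
    keep[ext$idx %in% drop_idx] <- FALSE
  }
  final <- ext[keep, , drop = FALSE]
  time[final$idx[final$type == "peak"]]
}

# product-of-variances weighting (the printed fusion form), used as the
# independent oracle against the inverse-variance implementation
product_form_fusion <- function(rr, sigma2) {
  n <- length(rr)
  prods <- vapply(seq_len(n), function(k) prod(sigma2[-k]), numeric(1))
  sum(prods * rr) / sum(prods)
}

short_session <- function(seed = 1, profile = "moderate", n_subcarriers = 256,
                          schedule = make_schedule(9, 3, 12, 60),
                          jitter = 0.5) {
  synth_session(schedule,
    profile = profile, seed = seed,
    n_subcarriers = n_subcarriers, jitter = jitter
  )
}
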