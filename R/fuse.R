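#' Create a one-dimensional Kalman source state
#'
#' Each fusion source (a PCA-component rank) carries a scalar random-walk
#' Kalman filter over its RR estimates. The state is the filtered RR; the
#' process noise models the slow drift of breathing rate between windows.
#'
#' @param state_estimate Initial RR, brpm.
#' @param error_variance Initial error variance, brpm^2.
#' @param process_variance Random-walk variance added per 1 s step,
#'   brpm^2 (default 0.1, matching paced protocols that change by at most
#'   3 brpm every two minutes).
#' @return A `kalman_state`.
#' @export
new_kalman_state <- function(state_estimate, error_variance,
                             process_variance = 0.1) {
  stopifnot(error_variance > 0, is.finite(state_estimate))
  structure(
    list(
      state_estimate = state_estimate, error_variance = error_variance,
      process_variance = process_variance, innovation = NA_real_
    ),
    class = "kalman_state"
  )
}

#' One predict/update step of the scalar Kalman filter
#'
#' Random-walk predict (the error variance grows by the process variance)
#' followed, if a measurement is supplied, by the standard scalar update.
#' An absent measurement (`NA`) performs the predict step only.
#'
#' @param state A `kalman_state`.
#' @param measurement RR measurement, brpm, or `NA` for predict-only.
#' @param measurement_variance Variance of the measurement, brpm^2 (> 0).
#' @return The updated `kalman_state`; `innovation` holds the pre-update
#'   measurement residual.
#' @export
kalman_step <- function(state, measurement, measurement_variance = 1) {
  stopifnot(inherits(state, "kalman_state"))
  p <- state$error_variance + state$process_variance
  if (is.na(measurement)) {
    state$error_variance <- p
    state$innovation <- NA_real_
    return(state)
  }
  stopifnot(measurement_variance > 0)
  innov <- measurement - state$state_estimate
  gain <- p / (p + measurement_variance)
  state$innovation <- innov
  state$state_estimate <- state$state_estimate + gain * innov
  state$error_variance <- (1 - gain) * p
  state
}

#' Effective variance of a fusion source
#'
#' `sigma^2 = r / SQI^2`, where `r` is the source's Kalman residual error
#' and SQI its current signal quality. A zero SQI yields an infinite
#' variance: the source is excluded from fusion for that window.
#'
#' @param residual Kalman residual error, brpm^2 (>= 0).
#' @param sqi Signal quality index in [0, 1].
#' @return Variance in brpm^2 (possibly `Inf`).
#' @export
source_variance <- function(residual, sqi) {
  stopifnot(residual >= 0, sqi >= 0, sqi <= 1)
  if (sqi == 0) {
    return(Inf)
  }
  residual / sqi^2
}

#' Fuse one window of RR estimates by inverse-variance weighting
#'
#' The fused estimate is the inverse-variance weighted mean of the sources
#' with finite variance, algebraically identical to the product-of-variances
#' weighting of multi-source Kalman fusion. Sources with infinite variance
#' are dropped before weighting; with no usable source the window is
#' invalid.
#'
#' @param rr RR estimates, brpm.
#' @param sigma2 Matching variances, brpm^2 (`Inf` excludes a source).
#' @return List with `rr` (fused, or `NA`), `weights` (normalised, zero for
#'   excluded sources), `variance` (of the fused estimate), `n_used`.
#' @export
fuse_window <- function(rr, sigma2) {
  stopifnot(length(rr) == length(sigma2), all(sigma2 > 0))
  usable <- is.finite(sigma2) & !is.na(rr)
  weights <- rep(0, length(rr))
  if (!any(usable)) {
    return(list(rr = NA_real_, weights = weights, variance = NA_real_, n_used = 0L))
  }
  inv <- 1 / sigma2[usable]
  weights[usable] <- inv / sum(inv)
  list(
    rr = sum(weights[usable] * rr[usable]),
    weights = weights,
    variance = 1 / sum(inv),
    n_used = sum(usable)
  )
}

# Fold sources measuring a harmonic of a higher-variance source down to the
# fundamental. Candidates are visited in increasing variance rank; a
# candidate within `tol` brpm of 2x or 3x an already-visited usable
# candidate's RR is divided by that multiple.
fold_harmonics <- function(cand, tol) {
  ord <- order(cand$rank)
  rrs <- cand$rr_combined[ord]
  sqis <- cand$sqi[ord]
  for (i in seq_along(rrs)) {
    if (is.na(rrs[i]) || sqis[i] <= 0 || i == 1) next
    for (mult in c(2, 3)) {
      ref <- rrs[seq_len(i - 1)]
      ok <- !is.na(ref) & sqis[seq_len(i - 1)] > 0 &
        abs(rrs[i] - mult * ref) <= tol
      if (any(ok)) {
        rrs[i] <- rrs[i] / mult
        break
      }
    }
  }
  cand$rr_combined[ord] <- rrs
  cand
}

#' Fuse per-window RR candidates into a 1 Hz series
#'
#' Maintains one scalar Kalman filter per component rank across windows
#' (rank after quality sorting defines the source identity). In each window
#' every source with a valid candidate and positive SQI is updated with its
#' combined RR estimate, using a measurement variance of
#' `base_variance / SQI^2`; its effective variance is the Kalman residual
#' divided by SQI^2, and the per-source filtered estimates are combined by
#' inverse-variance weighting. Sources without a usable candidate run a
#' predict-only step; windows with no usable source emit `valid = FALSE`.
#'
#' @param candidates Tibble of per-window candidates with columns `time`,
#'   `rank`, `rr_combined`, `sqi` (e.g. rows of [estimate_components()]
#'   stamped with their window end time).
#' @param process_variance Random-walk process variance, brpm^2 per step.
#' @param base_variance Measurement variance at SQI = 1, brpm^2.
#' @param band Physiological band, brpm; sets the initial error variance
#'   `((high - low) / 4)^2` of a freshly initialised source.
#' @param residual Which Kalman quantity plays the residual-error role:
#'   `"posterior"` (the posterior error variance, default) or
#'   `"innovation"` (the squared innovation).
#' @param harmonic_tolerance Tolerance (brpm) of the harmonic-folding guard,
#'   or `0` to disable it. PCA can split a non-sinusoidal breath across
#'   components: the fundamental lands in the high-variance components and
#'   its harmonics, as spectrally purer tones, in lower-variance ones. A
#'   source whose RR lies within this tolerance of 2 or 3 times the RR of a
#'   usable higher-variance source is re-interpreted as that harmonic and
#'   folded down (divided by the multiple) before its Kalman update.
#' @return A tibble of class `rr_series`: `time`, `rr`, `valid`,
#'   `sources_used`, `fused_variance`.
#' @export
fuse_session <- function(candidates, process_variance = 0.1,
                         base_variance = 1, band = c(5, 35),
                         residual = c("posterior", "innovation"),
                         harmonic_tolerance = 4) {
  residual <- match.arg(residual)
  stopifnot(all(c("time", "rank", "rr_combined", "sqi") %in% names(candidates)))
  times <- sort(unique(candidates$time))
  p0 <- ((band[2] - band[1]) / 4)^2
  states <- list()
  by_time <- split(candidates, candidates$time)
  out <- purrr::map_dfr(times, function(tt) {
    cand <- by_time[[as.character(tt)]]
    if (harmonic_tolerance > 0) {
      cand <- fold_harmonics(cand, harmonic_tolerance)
    }
    usable_ranks <- cand$rank[!is.na(cand$rr_combined) & cand$sqi > 0]
    rr_k <- numeric(0)
    s2_k <- numeric(0)
    n_used <- 0L
    seen <- names(states)
    # predict-only for known sources without a usable candidate this window
    for (r in seen) {
      if (!(as.numeric(r) %in% usable_ranks)) {
        states[[r]] <<- kalman_step(states[[r]], NA_real_)
      }
    }
    for (r in usable_ranks) {
      row <- cand[cand$rank == r, ][1, ]
      key <- as.character(r)
      mv <- base_variance / row$sqi^2
      if (is.null(states[[key]])) {
        states[[key]] <<- new_kalman_state(row$rr_combined, p0, process_variance)
        states[[key]] <<- kalman_step(states[[key]], row$rr_combined, mv)
      } else {
        states[[key]] <<- kalman_step(states[[key]], row$rr_combined, mv)
      }
      st <- states[[key]]
      res <- switch(residual,
        posterior = st$error_variance,
        innovation = max(st$innovation^2, .Machine$double.eps)
      )
      rr_k <- c(rr_k, st$state_estimate)
      s2_k <- c(s2_k, source_variance(res, row$sqi))
    }
    fused <- if (length(rr_k) > 0) {
      fuse_window(rr_k, s2_k)
    } else {
      list(rr = NA_real_, variance = NA_real_, n_used = 0L)
    }
    tibble::tibble(
      time = tt, rr = fused$rr, valid = !is.na(fused$rr),
      sources_used = fused$n_used, fused_variance = fused$variance
    )
  })
  class(out) <- c("rr_series", class(out))
  out
}
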