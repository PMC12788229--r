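#' Build a metronome pacing schedule
#'
#' A paced-breathing protocol is a staircase of breathing rates: it starts at
#' `start` breaths per minute (brpm), increases by `increment` brpm at fixed
#' intervals of `dwell` seconds, and stops after the level containing `end`.
#' The default arguments encode the protocol used throughout the package:
#' 6 brpm rising by 3 brpm every 120 s up to 33 brpm, a 20 minute session.
#'
#' @param start First paced rate, brpm.
#' @param increment Step size between consecutive levels, brpm. Must be > 0.
#' @param end Last paced rate, brpm. Must be >= `start`.
#' @param dwell Time each level is held, seconds. Must be > 0.
#'
#' @return A `metronome_schedule` object: a list with `start`, `increment`,
#'   `end`, `dwell`, `duration` (seconds) and `steps`, a tibble with one row
#'   per level (`onset` in seconds, `rate` in brpm).
#' @examples
#' sched <- make_schedule()
#' sched$duration / 60 # 20 minutes
#' rate_at(sched, 125) # 9 brpm: second level
#' @export
make_schedule <- function(start = 6, increment = 3, end = 33, dwell = 120) {
  if (!is.numeric(increment) || increment <= 0) {
    stop("`increment` must be a positive number of brpm", call. = FALSE)
  }
  if (!is.numeric(dwell) || dwell <= 0) {
    stop("`dwell` must be a positive number of seconds", call. = FALSE)
  }
  if (start > end) stop("`start` must not exceed `end`", call. = FALSE)
  rates <- seq(start, end, by = increment)
  steps <- tibble::tibble(
    onset = (seq_along(rates) - 1) * dwell,
    rate = rates
  )
  structure(
    list(
      start = start, increment = increment, end = end, dwell = dwell,
      duration = length(rates) * dwell, steps = steps
    ),
    class = "metronome_schedule"
  )
}

#' Paced rate at a given time
#'
#' Evaluates the schedule as a right-continuous step function: at the instant
#' a level change occurs the new rate applies. Times past the end of the
#' protocol return the final rate; negative times return `NA`.
#'
#' @param schedule A [make_schedule()] object.
#' @param t Time(s) in seconds (vectorised).
#' @return Paced rate(s) in brpm.
#' @export
rate_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "metronome_schedule"))
  idx <- pmin(floor(t / schedule$dwell) + 1, nrow(schedule$steps))
  out <- schedule$steps$rate[idx]
  out[t < 0] <- NA_real_
  out
}

#' @export
print.metronome_schedule <- function(x, ...) {
  cat(sprintf(
    "<metronome_schedule> %g to %g brpm by %g, %g s per level (%d levels, %g min)\n",
    x$start, x$end, x$increment, x$dwell, nrow(x$steps), x$duration / 60
  ))
  invisible(x)
}

#' Parse a compact schedule string
#'
#' Accepts `"start:increment:end:dwell"` (e.g. `"6:3:33:120"`), the format
#' used by the command-line helpers.
#'
#' @param text Schedule string.
#' @return A `metronome_schedule`.
#' @export
parse_schedule <- function(text) {
  parts <- suppressWarnings(as.numeric(strsplit(text, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 4 || anyNA(parts)) {
    stop("schedule string must be 'start:increment:end:dwell'", call. = FALSE)
  }
  make_schedule(parts[1], parts[2], parts[3], parts[4])
}
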