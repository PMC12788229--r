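#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

brpm_to_hz <- function(x) x / 60

# Strictly alternating local extrema of a numeric series. Plateaus are
# collapsed to their midpoint sample. Returns a tibble with columns
# idx, value, type ("peak"/"trough"), guaranteed to alternate.
find_extrema <- function(x) {
  n <- length(x)
  empty <- tibble::tibble(
    idx = integer(), value = numeric(), type = character()
  )
  if (n < 3) {
    return(empty)
  }
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) {
    return(empty)
  }
  s <- sign(d[nz])
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0) {
    return(empty)
  }
  # extremum lies between the end of one monotone run and the start of the
  # next; plateaus collapse to their midpoint sample
  idx <- as.integer(floor((nz[flip] + 1 + nz[flip + 1]) / 2))
  type <- ifelse(s[flip] > 0, "peak", "trough")
  tibble::tibble(idx = idx, value = x[idx], type = type)
}
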