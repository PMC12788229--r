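#' Write / read a CSI session
#'
#' A session is stored as a magnitude container plus a JSON metadata
#' sidecar (`<stem>.json`). Two containers are supported: `"csv"` (one row
#' per packet, one column per subcarrier, with a leading `time` column) and
#' `"bin"` (raw little-endian float32, row-major packets; the shape lives
#' in the sidecar). The sidecar records the sampling rate, subcarrier
#' count, session id, seed, schedule, and (for synthetic sessions) the 1 Hz
#' ground-truth RR.
#'
#' @param session A `csi_session`.
#' @param stem Output path without extension.
#' @param format `"csv"` or `"bin"`.
#' @return `write_csi_session()` returns the stem invisibly;
#'   `read_csi_session()` returns a `csi_session`.
#' @export
write_csi_session <- function(session, stem, format = c("csv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "csi_session"))
  meta <- session$metadata
  sidecar <- list(
    format = format,
    sampling_rate = meta$sampling_rate,
    n_subcarriers = ncol(session$magnitudes),
    n_packets = nrow(session$magnitudes),
    session_id = meta$session_id,
    seed = meta$seed,
    schedule = if (!is.null(meta$schedule)) {
      with(meta$schedule, sprintf("%g:%g:%g:%g", start, increment, end, dwell))
    },
    ground_truth_rr = if (!is.null(meta$ground_truth)) meta$ground_truth$rr,
    ground_truth_time = if (!is.null(meta$ground_truth)) meta$ground_truth$time
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (format == "csv") {
    df <- data.frame(time = session$timestamps, session$magnitudes)
    names(df) <- c("time", sprintf("sc%03d", seq_len(ncol(session$magnitudes))))
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  } else {
    con <- file(paste0(stem, ".bin"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(session$timestamps), con, size = 4, endian = "little")
    writeBin(as.numeric(t(session$magnitudes)), con, size = 4, endian = "little")
  }
  invisible(stem)
}

#' @rdname write_csi_session
#' @export
read_csi_session <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  k <- meta$n_subcarriers
  if (identical(meta$format, "bin")) {
    con <- file(paste0(stem, ".bin"), "rb")
    on.exit(close(con))
    n <- meta$n_packets
    ts <- readBin(con, numeric(), n, size = 4, endian = "little")
    mags <- matrix(
      readBin(con, numeric(), n * k, size = 4, endian = "little"),
      nrow = n, ncol = k, byrow = TRUE
    )
  } else {
    df <- utils::read.csv(paste0(stem, ".csv"))
    ts <- df$time
    mags <- as.matrix(df[, -1, drop = FALSE])
    dimnames(mags) <- NULL
  }
  gt <- NULL
  if (!is.null(meta$ground_truth_rr)) {
    gt <- tibble::tibble(time = meta$ground_truth_time, rr = meta$ground_truth_rr)
  }
  new_csi_session(mags, ts, list(
    sampling_rate = meta$sampling_rate, n_subcarriers = k,
    session_id = meta$session_id, seed = meta$seed,
    schedule = if (!is.null(meta$schedule)) parse_schedule(meta$schedule),
    ground_truth = gt
  ))
}

#' Write / read an airflow trace (single-column CSV + JSON sidecar)
#'
#' @param trace An `airflow_trace`.
#' @param stem Output path without extension.
#' @return `write_airflow()` returns the stem invisibly; `read_airflow()`
#'   an `airflow_trace`.
#' @export
write_airflow <- function(trace, stem) {
  stopifnot(inherits(trace, "airflow_trace"))
  jsonlite::write_json(
    list(sampling_rate = trace$sampling_rate, n_samples = length(trace$pressure)),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(
    data.frame(pressure = trace$pressure), paste0(stem, ".csv"),
    row.names = FALSE
  )
  invisible(stem)
}

#' @rdname write_airflow
#' @export
read_airflow <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  p <- utils::read.csv(paste0(stem, ".csv"))$pressure
  new_airflow_trace(p, (seq_along(p) - 1) / meta$sampling_rate, meta$sampling_rate)
}

#' Write / read an RR series as CSV
#'
#' Columns `time`, `rr`, `valid` (plus any extras such as `sources_used`).
#'
#' @param series An `rr_series` tibble.
#' @param path Output CSV path.
#' @return `write_rr_series()` returns `path` invisibly; `read_rr_series()`
#'   the series tibble.
#' @export
write_rr_series <- function(series, path) {
  utils::write.csv(tibble::as_tibble(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_series
#' @export
read_rr_series <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  df$valid <- as.logical(df$valid)
  class(df) <- c("rr_series", class(df))
  df
}
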