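#' Pair an estimated RR series with a reference series
#'
#' Joins two 1 Hz `rr_series` on their timestamps and keeps only the pairs
#' where both are valid. The numbers of samples dropped on each side are
#' attached as attributes (`dropped_est`, `dropped_ref`).
#'
#' @param est,ref `rr_series` tibbles (`time`, `rr`, `valid`).
#' @return Tibble with columns `time`, `est`, `ref`.
#' @export
align_series <- function(est, ref) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(est),
      time = "time", est = "rr", est_valid = "valid"
    ),
    dplyr::select(tibble::as_tibble(ref),
      time = "time", ref = "rr", ref_valid = "valid"
    ),
    by = "time"
  )
  if (nrow(joined) == 0) stop("series do not overlap in time", call. = FALSE)
  pairs <- dplyr::filter(joined, .data$est_valid & .data$ref_valid)
  if (nrow(pairs) == 0) {
    stop("no window is valid in both series", call. = FALSE)
  }
  out <- dplyr::select(pairs, "time", "est", "ref")
  attr(out, "dropped_est") <- sum(!joined$est_valid)
  attr(out, "dropped_ref") <- sum(!joined$ref_valid)
  out
}

compute_metrics <- function(est, ref) {
  d <- est - ref
  n <- length(d)
  r2 <- if (n >= 2 && stats::var(ref) > 0 && stats::var(est) > 0) {
    stats::cor(est, ref)^2
  } else {
    NA_real_
  }
  sd_d <- if (n >= 2) stats::sd(d) else NA_real_
  bias <- mean(d)
  list(
    mae = mean(abs(d)), rmse = sqrt(mean(d^2)), r_squared = r2,
    bias = bias, sd_diff = sd_d,
    loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
    rr2brpm = 100 * mean(abs(d) <= 2), n = n
  )
}

#' Agreement metrics between estimated and reference RR
#'
#' Computes the package's full agreement panel: mean absolute error, root
#' mean squared error, squared Pearson correlation, Bland-Altman bias
#' (estimate minus reference) with 1.96-SD limits of agreement, and the
#' percentage of estimates within +/-2 brpm of the reference.
#'
#' @param pairs Output of [align_series()] (columns `est`, `ref`), with at
#'   least two rows.
#' @return An `agreement_report` object. Use [tidy()] / [glance()] for
#'   tabular access and [autoplot()] for the Bland-Altman plot.
#' @export
agreement_metrics <- function(pairs) {
  stopifnot(all(c("est", "ref") %in% names(pairs)), nrow(pairs) >= 2)
  structure(
    c(compute_metrics(pairs$est, pairs$ref), list(pairs = tibble::as_tibble(pairs))),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  n windows : %d\n", x$n))
  cat(sprintf("  MAE       : %.2f brpm\n", x$mae))
  cat(sprintf("  RMSE      : %.2f brpm\n", x$rmse))
  cat(sprintf("  r-squared : %s\n", formatC(x$r_squared, digits = 3, format = "f")))
  cat(sprintf(
    "  bias      : %+.2f brpm (LoA %.2f to %.2f)\n",
    x$bias, x$loa_low, x$loa_high
  ))
  cat(sprintf("  within 2  : %.1f%%\n", x$rr2brpm))
  invisible(x)
}

#' @rdname agreement_metrics
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    metric = c(
      "mae", "rmse", "r_squared", "bias", "loa_low", "loa_high",
      "rr2brpm", "n"
    ),
    value = c(
      x$mae, x$rmse, x$r_squared, x$bias, x$loa_low, x$loa_high,
      x$rr2brpm, x$n
    )
  )
}

#' @rdname agreement_metrics
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    mae = x$mae, rmse = x$rmse, r_squared = x$r_squared, bias = x$bias,
    loa_low = x$loa_low, loa_high = x$loa_high, rr2brpm = x$rr2brpm,
    n = x$n
  )
}

#' Bland-Altman plot of an agreement report
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot: paired differences against paired means, with the bias
#'   and 1.96-SD limits of agreement.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- dplyr::mutate(object$pairs,
    mean_rr = (.data$est + .data$ref) / 2,
    diff_rr = .data$est - .data$ref
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rr, y = .data$diff_rr)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Mean of estimate and reference (brpm)",
      y = "Estimate - reference (brpm)",
      title = "Bland-Altman agreement"
    )
}

#' Agreement metrics stratified by RR band
#'
#' Assigns each pair to a band by the *mean* of estimate and reference
#' (lower band edges inclusive: with the default edges the bands are
#' `< 12`, `[12, 21)` and `>= 21` brpm) and computes the agreement panel
#' per band. Empty bands are reported with `n = 0` and missing metrics.
#'
#' @param pairs Output of [align_series()].
#' @param band_edges Interior band edges, brpm (default `c(12, 21)`).
#' @return Tibble with one row per band: `band`, `n`, `mae`, `rmse`,
#'   `r_squared`, `bias`, `loa_low`, `loa_high`, `rr2brpm`.
#' @export
banded_report <- function(pairs, band_edges = c(12, 21)) {
  stopifnot(all(c("est", "ref") %in% names(pairs)))
  edges <- c(-Inf, sort(band_edges), Inf)
  labels <- character(length(edges) - 1)
  for (i in seq_along(labels)) {
    labels[i] <- if (i == 1) {
      sprintf("<%g", edges[2])
    } else if (i == length(labels)) {
      sprintf(">=%g", edges[i])
    } else {
      sprintf("%g-%g", edges[i], edges[i + 1])
    }
  }
  mid <- (pairs$est + pairs$ref) / 2
  band <- cut(mid, edges, labels = labels, right = FALSE)
  purrr::map_dfr(labels, function(b) {
    sub <- pairs[!is.na(band) & band == b, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        band = b, n = 0L, mae = NA_real_, rmse = NA_real_,
        r_squared = NA_real_, bias = NA_real_, loa_low = NA_real_,
        loa_high = NA_real_, rr2brpm = NA_real_
      ))
    }
    m <- compute_metrics(sub$est, sub$ref)
    tibble::tibble(
      band = b, n = m$n, mae = m$mae, rmse = m$rmse,
      r_squared = m$r_squared, bias = m$bias, loa_low = m$loa_low,
      loa_high = m$loa_high, rr2brpm = m$rr2brpm
    )
  })
}

#' Plot an RR series
#'
#' @param object An `rr_series` tibble (`time`, `rr`, `valid`).
#' @param ... Unused.
#' @return A ggplot of RR against time; invalid windows are shown hollow.
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time / 60, y = .data$rr, alpha = .data$valid)
  ) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15), guide = "none") +
    ggplot2::labs(x = "Time (min)", y = "RR (brpm)")
}
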