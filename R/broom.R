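#' @export
print.vn_fit <- function(x, ...) {
  cat("Virtual-normal fit\n")
  cat("  variant:   ", x$config$variant,
      " (statistic: ", x$config$statistic, ")\n", sep = "")
  cat("  markers:   ", nrow(x$map), " (", sum(!x$mask), " masked)\n",
      sep = "")
  cat("  samples:   ", length(unique(x$qc$sample)), " test\n", sep = "")
  cat("  mean segmented SD (log2): ",
      signif(mean(x$qc$segmented_sd, na.rm = TRUE), 4), "\n", sep = "")
  cat("  mean S/N (CN=3):          ",
      signif(mean(x$qc$snr_cn3, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a virtual-normal fit into its per-sample segment table
#'
#' @param x A `vn_fit` from [run_vn()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, segment): `sample`, `chrom`,
#'   `start`, `end`, `n_markers`, `level`, and `call`
#'   (`gain`/`loss`/`neutral` at the +/- 0.2 log2 threshold).
#' @export
tidy.vn_fit <- function(x, ...) {
  seg <- tibble::as_tibble(x$segments)
  seg$call <- dplyr::case_when(seg$level > 0.2 ~ "gain",
                               seg$level < -0.2 ~ "loss",
                               TRUE ~ "neutral")
  seg[c("sample", "chrom", "start", "end", "n_markers", "level", "call")]
}

#' One-row summary of a virtual-normal fit
#'
#' @param x A `vn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample/marker counts, variant, mean segmented
#'   SD and mean CN=3 S/N over samples, and the call count beyond 0.2.
#' @export
glance.vn_fit <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$map),
    n_masked = sum(!x$mask),
    n_test = length(unique(x$qc$sample)),
    variant = x$config$variant,
    statistic = x$config$statistic,
    gc_correct = x$config$gc_correct,
    mean_segmented_sd = mean(x$qc$segmented_sd, na.rm = TRUE),
    mean_snr_cn3 = mean(x$qc$snr_cn3, na.rm = TRUE),
    n_calls = sum(abs(x$segments$level) > 0.2))
}

#' @export
tidy.vn_refrun <- function(x, ...) tidy.vn_fit(x, ...)

#' Plot raw CN and segmentation for one sample of a fit
#'
#' Scatter of the per-marker raw CN signal with segment levels overlaid and
#' the +/- 0.2 log2 call thresholds, one panel per chromosome — the standard
#' per-sample view for judging noise and calls.
#'
#' @param object A `vn_fit` (or `run_reference()` result).
#' @param sample Sample id to plot (default: first).
#' @param threshold Call threshold drawn as dashed lines (default 0.2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vn_fit <- function(object, sample = NULL, threshold = 0.2, ...) {
  sm <- sample %||% object$raw_cn$sample[1]
  d <- object$raw_cn[object$raw_cn$sample == sm, , drop = FALSE]
  seg <- object$segments[object$segments$sample == sm, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3, colour = "grey40",
                        na.rm = TRUE) +
    ggplot2::geom_segment(
      data = tibble::as_tibble(seg),
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$level, yend = .data$level),
      colour = "red", linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "blue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "raw CN (log2 ratio)",
                  title = paste0("Raw CN, sample ", sm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vn_refrun <- function(object, ...) autoplot.vn_fit(object, ...)

#' Plot a virtual reference against the test-set average
#'
#' Shows the baseline-shift function S(p) that was removed from the test-set
#' average to produce the reference.
#'
#' @param object A `vn_reference`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vn_reference <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$s)) +
    ggplot2::geom_step(colour = "red", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "baseline shift S(p) (log2)",
                  title = "Shift removed from test-set average") +
    ggplot2::theme_minimal()
}
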