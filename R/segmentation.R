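#' @keywords internal
new_segments <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("vn_segments", class(df))
  df
}

## robust per-chromosome noise scale from successive differences;
## insensitive to step changes as long as breakpoints are sparse
.noise_sigma <- function(x) {
  if (length(x) < 2) return(0)
  s <- median(abs(diff(x))) / (sqrt(2) * qnorm(0.75))
  if (!is.finite(s) || s <= 0) s <- sd(x)
  if (!is.finite(s)) s <- 0
  s
}

## breakpoints (index of last marker of the left flank) by recursive binary
## splitting; ties in the z statistic go to the leftmost candidate
.segment_indices <- function(x, z_min, min_seg, max_depth, sigma) {
  n <- length(x)
  bps <- integer(0)
  if (n < 2L * min_seg || sigma <= 0) return(bps)
  recurse <- function(lo, hi, depth) {
    m <- hi - lo + 1L
    if (depth <= 0L || m < 2L * min_seg) return(invisible(NULL))
    cs <- cumsum(x[lo:hi])
    tot <- cs[m]
    k <- min_seg:(m - min_seg)
    nl <- k
    nr <- m - k
    z <- abs(cs[k] / nl - (tot - cs[k]) / nr) /
      (sigma * sqrt(1 / nl + 1 / nr))
    if (max(z) >= z_min) {
      bp <- lo + k[which.max(z)] - 1L
      bps <<- c(bps, bp)
      recurse(lo, bp, depth - 1L)
      recurse(bp + 1L, hi, depth - 1L)
    }
    invisible(NULL)
  }
  recurse(1L, n, max_depth)
  sort(bps)
}

#' Mean-preserving piecewise-constant segmentation
#'
#' Recursive binary segmentation per chromosome.  At each step the candidate
#' split maximizing the standardized difference of flank means
#' \eqn{z = |m_L - m_R| / (\sigma \sqrt{1/n_L + 1/n_R})} is accepted when
#' \eqn{z \ge z_{min}}; \eqn{\sigma} is estimated robustly from successive
#' marker differences.  Each final segment's level is exactly the arithmetic
#' mean of the profile inside it, so segmentation preserves segment means by
#' construction.  Chromosomes shorter than twice the minimum segment length
#' come back as a single segment; fully masked chromosomes are dropped.
#'
#' @param profile A profile tibble (`marker_id`, `chrom`, `pos`, `value`);
#'   `NA` values are treated as masked and skipped.
#' @param z_min Split acceptance threshold on the z statistic (default 4).
#' @param min_seg Minimum segment length in markers (default 5, must be >= 2).
#' @param max_depth Maximum recursion depth (default 30).
#' @param sample Optional sample label stored in the output.
#' @return A `vn_segments` tibble: `sample`, `chrom`, `start`, `end`
#'   (positions, 1-based inclusive), `n_markers`, `level` (log2), plus the
#'   marker-map row span `first_row`/`last_row` within the unmasked scaffold.
#' @export
segment_profile <- function(profile, z_min = 4, min_seg = 5, max_depth = 30,
                            sample = NULL) {
  stopifnot(min_seg >= 2, z_min > 0)
  label <- sample %||% attr(profile, "label") %||% "sample"
  keep <- is.finite(profile$value)
  out <- profile[keep, , drop = FALSE] |>
    dplyr::mutate(.row = which(keep)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      x <- d$value
      sigma <- .noise_sigma(x)
      bps <- .segment_indices(x, z_min, min_seg, max_depth, sigma)
      lo <- c(1L, bps + 1L)
      hi <- c(bps, length(x))
      tibble::tibble(
        sample = label, chrom = key$chrom[[1]],
        start = d$pos[lo], end = d$pos[hi],
        n_markers = hi - lo + 1L,
        level = vapply(seq_along(lo),
                       function(i) mean(x[lo[i]:hi[i]]), numeric(1)),
        first_row = d$.row[lo], last_row = d$.row[hi])
    }) |>
    dplyr::bind_rows()
  new_segments(out)
}

## truncated Gaussian kernel weights for a window of w markers
.gauss_kernel <- function(w) {
  h <- max(1L, floor(w / 2))
  k <- dnorm(seq(-h, h), sd = w / 4)
  k / sum(k)
}

#' Gaussian-window smoothing as a degenerate piecewise profile
#'
#' Per-marker moving Gaussian average (sd = `w`/4, truncated at half the
#' window width, renormalized at chromosome edges so weights always sum to 1).
#' Windows never span chromosome boundaries.  The result is returned in the
#' same form as [segment_profile()] — one degenerate single-marker segment per
#' marker — so either estimator can serve as the baseline-shift function in
#' the virtual-normal construction.  Chromosomes shorter than 3 markers pass
#' through unchanged.
#'
#' @inheritParams segment_profile
#' @param w Window width in markers (default 20, must be >= 3).
#' @return A `vn_segments` tibble with one row per unmasked marker.
#' @export
smooth_profile <- function(profile, w = 20, sample = NULL) {
  stopifnot(w >= 3)
  label <- sample %||% attr(profile, "label") %||% "sample"
  kern <- .gauss_kernel(w)
  h <- (length(kern) - 1L) %/% 2L
  keep <- is.finite(profile$value)
  out <- profile[keep, , drop = FALSE] |>
    dplyr::mutate(.row = which(keep)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      x <- d$value
      n <- length(x)
      if (n < 3L) {
        sm <- x
      } else {
        num <- convolve(x, rev(kern), type = "open")[(h + 1):(h + n)]
        den <- convolve(rep(1, n), rev(kern), type = "open")[(h + 1):(h + n)]
        sm <- num / den
      }
      tibble::tibble(sample = label, chrom = key$chrom[[1]],
                     start = d$pos, end = d$pos,
                     n_markers = 1L, level = sm,
                     first_row = d$.row, last_row = d$.row)
    }) |>
    dplyr::bind_rows()
  new_segments(out)
}

#' Evaluate a piecewise profile at the markers of a map
#'
#' @param segments A `vn_segments` tibble.
#' @param map A marker map (or any tibble with `chrom` and `pos`).
#' @return Numeric vector of levels, one per map row; `NA` where no segment
#'   covers the marker.
#' @export
eval_segments <- function(segments, map) {
  out <- rep(NA_real_, nrow(map))
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    rows <- which(map$chrom == ch)
    if (length(rows) == 0) next
    idx <- findInterval(map$pos[rows], seg$start)
    ok <- idx >= 1L
    ok[ok] <- map$pos[rows][ok] <= seg$end[idx[ok]]
    out[rows[ok]] <- seg$level[idx[ok]]
  }
  out
}
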