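#' Segmented-region standard deviation of a raw CN profile
#'
#' The noise metric used for reference-quality comparison: within each
#' segment, the SD of the raw CN values around the segment level; reported as
#' the unweighted mean over segments ("average of all SDs"), in log2.
#' Single-marker segments carry no spread and are excluded.  A marker-count
#' weighted variant is available.
#'
#' @param profile A profile tibble (`chrom`, `pos`, `value`).
#' @param segments A `vn_segments` covering the profile.
#' @param weighted If `TRUE`, weight segment SDs by marker count.
#' @return A single SD in log2 units.
#' @export
segmented_sd <- function(profile, segments, weighted = FALSE) {
  lev <- eval_segments(segments, profile)
  d <- tibble::tibble(chrom = profile$chrom, pos = profile$pos,
                      value = profile$value, lev = lev)
  d <- d[is.finite(d$value) & is.finite(d$lev), , drop = FALSE]
  per_seg <- purrr::map_dbl(seq_len(nrow(segments)), function(i) {
    sel <- d$chrom == segments$chrom[i] &
      d$pos >= segments$start[i] & d$pos <= segments$end[i]
    if (sum(sel) < 2) return(NA_real_)
    sd(d$value[sel])
  })
  w <- segments$n_markers
  ok <- is.finite(per_seg)
  if (!any(ok)) return(NA_real_)
  if (weighted) {
    sum(per_seg[ok] * w[ok]) / sum(w[ok])
  } else {
    mean(per_seg[ok])
  }
}

#' Signal-to-noise ratio for a single-copy gain (CN = 3 vs CN = 2)
#'
#' The separation between the log2 raw-CN levels of three and two copies,
#' divided by the segmented-region SD.  The default uses the theoretical
#' levels, `log2(3) - log2(2) = 0.585`; [snr_cn3_measured()] accepts observed
#' segment means instead, for data where aberrant-cell fraction or intensity
#' compression move the measured levels off theory.
#'
#' @param sd Segmented-region SD (log2); vectorized.
#' @return S/N ratio; `Inf` with a warning when `sd` is 0.
#' @export
snr_cn3 <- function(sd) {
  if (any(sd == 0, na.rm = TRUE)) {
    warn("sd = 0: S/N undefined, reporting Inf")
  }
  (log2(3) - log2(2)) / sd
}

#' @rdname snr_cn3
#' @param cn3_mean,cn2_mean Observed raw CN segment means (log2) for regions
#'   at three and two copies.
#' @export
snr_cn3_measured <- function(cn3_mean, cn2_mean, sd) {
  if (any(sd == 0, na.rm = TRUE)) {
    warn("sd = 0: S/N undefined, reporting Inf")
  }
  (cn3_mean - cn2_mean) / sd
}

## marker indices (rows of map) covered by calls beyond the threshold
.called_rows <- function(segments, map, threshold) {
  calls <- segments[abs(segments$level) > threshold, , drop = FALSE]
  if (nrow(calls) == 0) return(integer(0))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    which(map$chrom == calls$chrom[i] &
            map$pos >= calls$start[i] & map$pos <= calls$end[i])
  })
  sort(unique(unlist(rows)))
}

#' Concordance between two segmentation call sets
#'
#' Calls are segments with |level| beyond `threshold` (default 0.2 log2, the
#' standard gain/loss call threshold).  Reports the marker-weighted Jaccard
#' index of the called territories and event-level agreement by reciprocal
#' overlap.
#'
#' @param a,b `vn_segments` tibbles on the same marker map.
#' @param map The shared marker map.
#' @param threshold Absolute log2 call threshold (default 0.2).
#' @param min_overlap Reciprocal-overlap fraction for event matching.
#' @return A list: `jaccard`, `n_calls_a`, `n_calls_b`, `n_matched_events`.
#' @export
concordance <- function(a, b, map, threshold = 0.2, min_overlap = 0.5) {
  ra <- .called_rows(a, map, threshold)
  rb <- .called_rows(b, map, threshold)
  uni <- length(union(ra, rb))
  jac <- if (uni == 0) 1 else length(intersect(ra, rb)) / uni
  calls_a <- a[abs(a$level) > threshold, , drop = FALSE]
  calls_b <- b[abs(b$level) > threshold, , drop = FALSE]
  seg_rows <- function(calls, i) {
    which(map$chrom == calls$chrom[i] &
            map$pos >= calls$start[i] & map$pos <= calls$end[i])
  }
  matched <- 0L
  used_b <- rep(FALSE, nrow(calls_b))
  for (i in seq_len(nrow(calls_a))) {
    ra_i <- seg_rows(calls_a, i)
    for (j in which(!used_b & calls_b$chrom == calls_a$chrom[i])) {
      rb_j <- seg_rows(calls_b, j)
      ov <- length(intersect(ra_i, rb_j))
      if (ov == 0) next
      la <- length(ra_i)
      lb <- length(rb_j)
      if (ov / la >= min_overlap && ov / lb >= min_overlap) {
        matched <- matched + 1L
        used_b[j] <- TRUE
        break
      }
    }
  }
  list(jaccard = jac, n_calls_a = nrow(calls_a), n_calls_b = nrow(calls_b),
       n_matched_events = matched)
}
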