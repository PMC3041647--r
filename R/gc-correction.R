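#' @keywords internal
new_gc_model <- function(bins, sigma_resid = NA_real_) {
  bins <- tibble::as_tibble(bins)[c("bin_low", "bin_high", "n", "level")]
  structure(bins, sigma_resid = sigma_resid,
            class = c("vn_gc_model", class(bins)))
}

#' Fit an aberration-tolerant GC-wave model
#'
#' Slow hybridization-intensity waves correlated with local GC content are
#' estimated as per-bin medians of the log2-ratio profile over equal-width GC
#' bins, then mean-centered with marker-count weights so applying the model
#' never shifts the genome-wide mean.  The median is the aberration-tolerance
#' mechanism: amplified and deleted regions stay in the fit (no aberration
#' pre-filtering) but cannot dominate any bin they do not own outright.  Bins
#' with fewer than `min_bin` markers are merged into their neighbor.
#'
#' @param profile A profile tibble (`marker_id`, `chrom`, `pos`, `gc`,
#'   `value`); masked (`NA`) markers are ignored in the fit.
#' @param nbins Number of equal-width GC bins over the observed GC range
#'   (default 50).
#' @param min_bin Minimum unmasked markers a bin must hold to stand on its
#'   own (default 10).
#' @param exclude_chroms Chromosomes excluded from fitting (copy state
#'   differs on sex chromosomes); they are still corrected on application.
#' @return A `vn_gc_model`: tibble of `bin_low`, `bin_high`, `n`, `level`
#'   (log2), with a residual-spread diagnostic attribute.
#' @export
fit_gc_wave <- function(profile, nbins = 50, min_bin = 10,
                        exclude_chroms = c("X", "Y", "chrX", "chrY")) {
  d <- profile[is.finite(profile$value) &
                 !(profile$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(d) < 2 * min_bin) abort("too few unmasked markers to fit GC wave")
  rng <- range(d$gc)
  if (diff(rng) == 0) {
    # constant GC: a single bin, centered to zero by construction
    bins <- tibble::tibble(bin_low = rng[1], bin_high = rng[2],
                           n = nrow(d), level = 0)
    return(new_gc_model(bins, sigma_resid = sd(d$value)))
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  idx <- findInterval(d$gc, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nbins)

  bins <- tibble::tibble(bin = seq_len(nbins),
                         bin_low = breaks[-length(breaks)],
                         bin_high = breaks[-1])
  # merge under-filled bins into the next non-empty neighbor (rightward,
  # last bin merges leftward) until every retained bin holds >= min_bin
  group <- seq_len(nbins)
  repeat {
    counts <- tabulate(match(group[idx], unique(group)),
                       nbins = length(unique(group)))
    ug <- unique(group)
    small <- ug[counts < min_bin]
    if (length(small) == 0) break
    g <- small[1]
    pos_g <- which(ug == g)
    target <- if (pos_g < length(ug)) ug[pos_g + 1] else ug[pos_g - 1]
    group[group == g] <- target
    if (length(unique(group)) < 2) break
  }
  d$grp <- group[idx]
  fit <- d |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(level = median(.data$value), n = dplyr::n(),
                     .groups = "drop")
  ug <- sort(unique(group))
  if (nrow(fit) < 2) abort("fewer than 2 usable GC bins; no gradient estimable")
  merged <- tibble::tibble(
    grp = ug,
    bin_low = vapply(ug, function(g) min(bins$bin_low[group == g]),
                     numeric(1)),
    bin_high = vapply(ug, function(g) max(bins$bin_high[group == g]),
                      numeric(1))) |>
    dplyr::inner_join(fit, by = "grp") |>
    dplyr::arrange(.data$bin_low)
  merged$level <- merged$level -
    sum(merged$level * merged$n) / sum(merged$n)
  resid <- d$value - merged$level[match(d$grp, merged$grp)]
  new_gc_model(merged[c("bin_low", "bin_high", "n", "level")],
               sigma_resid = sd(resid))
}

#' Look up per-marker GC corrections from a fitted model
#'
#' @param model A `vn_gc_model`.
#' @param gc Numeric vector of GC fractions; values outside all bins take the
#'   nearest bin's level.
#' @return Numeric vector of log2 corrections.
#' @export
gc_correction_values <- function(model, gc) {
  lows <- model$bin_low
  idx <- findInterval(gc, lows)
  idx <- pmin(pmax(idx, 1L), nrow(model))
  model$level[idx]
}

#' Remove a fitted GC wave from a profile
#'
#' Subtracts the per-bin median correction from every unmasked marker
#' (sex chromosomes included); masks are unchanged.  Because the model is
#' mean-centered with the fit's marker counts, correction leaves the
#' weighted genome-wide mean of the profile intact.
#'
#' @param profile A profile tibble with `gc` and `value` columns.
#' @param model A `vn_gc_model` from [fit_gc_wave()].
#' @return The profile with corrected `value`.
#' @export
apply_gc_correction <- function(profile, model) {
  corr <- gc_correction_values(model, profile$gc)
  profile$value <- profile$value - corr
  profile
}

#' @export
tidy.vn_gc_model <- function(x, ...) {
  tibble::tibble(bin_low = x$bin_low, bin_high = x$bin_high,
                 n = x$n, level = x$level)
}

#' @export
autoplot.vn_gc_model <- function(object, ...) {
  d <- tidy(object)
  d$mid <- (d$bin_low + d$bin_high) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$level)) +
    ggplot2::geom_step(ggplot2::aes(x = .data$bin_low)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GC fraction (bin midpoint)",
                  y = "GC-wave level (log2)",
                  title = "Fitted GC wave (per-bin medians, mean-centered)") +
    ggplot2::theme_minimal()
}
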