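#' Per-marker average intensity of a sample set
#'
#' The reference-building statistic: for every marker, the median (default) or
#' mean intensity across the samples of the set, computed on the linear scale.
#' The median makes the average robust to aberrations carried by a minority
#' of samples; the mean lets minority events enter the average proportionally
#' to their carrier fraction.
#'
#' @param x An intensity tibble (`marker_id` + sample columns).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A tibble `marker_id`, `intensity`.
#' @export
average_intensity <- function(x, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (ncol(x) < 2) abort("intensity matrix has no sample columns")
  vals <- as.matrix(x[, -1, drop = FALSE])
  avg <- if (statistic == "median") {
    apply(vals, 1, median)
  } else {
    rowMeans(vals)
  }
  tibble::tibble(marker_id = as.character(x$marker_id), intensity = avg)
}

#' Log2 ratio of test-set and template-set average intensities
#'
#' The raw copy-number average signal: per marker,
#' \eqn{\log_2(I^t_{avg}(p) / I^r_{avg}(p))}.  This is the signal in which
#' aberrations common to the test set are located before being shifted out of
#' the virtual reference.
#'
#' @param t_avg,r_avg Per-marker average intensities (numeric vectors or
#'   tibbles from [average_intensity()]), positive wherever unmasked.
#' @param map A validated marker map.
#' @param mask Optional logical shared mask; masked markers get `NA`.
#' @return A profile tibble (`marker_id`, `chrom`, `pos`, `gc`, `value`).
#' @export
cn_average <- function(t_avg, r_avg, map, mask = NULL) {
  t_avg <- if (is.data.frame(t_avg)) t_avg$intensity else t_avg
  r_avg <- if (is.data.frame(r_avg)) r_avg$intensity else r_avg
  val <- log2(t_avg / r_avg)
  if (!is.null(mask)) val[!mask] <- NA_real_
  cn_profile(map, val, label = "CN average (test vs template)")
}

#' Construct the virtual reference intensity signal
#'
#' Shifts every segment of the test-set average back to baseline:
#' \eqn{I^{vn}(p) = I^t_{avg}(p) \cdot 2^{-S(p)}}, where `S(p)` is the
#' baseline-shift function estimated by mean-preserving segmentation or
#' Gaussian filtering of the (GC-corrected) average log2 ratio.  By
#' construction `log2(t_avg / I_vn)` equals `S(p)` exactly at every unmasked
#' marker.
#'
#' @param t_avg Per-marker test-set average intensity (vector or tibble).
#' @param s A `vn_segments` baseline-shift function covering all unmasked
#'   markers.
#' @param map A validated marker map.
#' @param meta Optional list of provenance fields (template id, variant,
#'   parameters) stored as an attribute.
#' @return A tibble `marker_id`, `chrom`, `pos`, `gc`, `intensity`, `s`,
#'   classed `vn_reference`.
#' @export
build_virtual_reference <- function(t_avg, s, map, meta = list()) {
  t_avg <- if (is.data.frame(t_avg)) t_avg$intensity else t_avg
  s_p <- eval_segments(s, map)
  unmasked <- is.finite(t_avg)
  if (any(unmasked & !is.finite(s_p))) {
    abort("baseline-shift function S(p) undefined at unmasked markers")
  }
  out <- tibble::tibble(marker_id = map$marker_id, chrom = map$chrom,
                        pos = map$pos, gc = map$gc,
                        intensity = t_avg * 2^(-s_p), s = s_p)
  attr(out, "meta") <- meta
  attr(out, "segments") <- s
  class(out) <- c("vn_reference", class(out))
  out
}

#' Raw copy-number signal of one sample against a reference
#'
#' Per-marker \eqn{\log_2(I_i(p) / I_{ref}(p))}, the raw CN signal before
#' segmentation, against either a virtual or a conventional average reference.
#'
#' @param sample_intensity Numeric vector of the sample's intensities.
#' @param reference_intensity Numeric vector (or `vn_reference` tibble) of
#'   reference intensities.
#' @param map A validated marker map.
#' @param label Sample label.
#' @return A profile tibble.
#' @export
raw_cn <- function(sample_intensity, reference_intensity, map,
                   label = "sample") {
  ref <- if (is.data.frame(reference_intensity)) {
    reference_intensity$intensity
  } else {
    reference_intensity
  }
  cn_profile(map, log2(sample_intensity / ref), label = label)
}

#' Virtual-normal run configuration
#'
#' @param variant `"segmentation"` (direct segment detection of the average
#'   ratio; highest resolution) or `"filter"` (Gaussian-window smoothing; the
#'   conservative choice when average-level noise makes false segments
#'   likely).
#' @param statistic Averaging statistic for the set averages, `"median"`
#'   (default) or `"mean"`.
#' @param gc_correct Apply GC-wave correction to the average ratio before
#'   estimating `S(p)` and to each per-sample raw CN before its final
#'   segmentation.
#' @param nbins GC bins for [fit_gc_wave()].
#' @param z_min,min_seg Segmentation parameters ([segment_profile()]), used
#'   for `S(p)` in the segmentation variant and always for the final
#'   per-sample segmentation.
#' @param w Smoothing window width in markers for the filter variant.
#' @param template_id Provenance label of the template set.
#' @return A list of class `vn_config`.
#' @export
vn_config <- function(variant = c("segmentation", "filter"),
                      statistic = c("median", "mean"),
                      gc_correct = TRUE, nbins = 50,
                      z_min = 4, min_seg = 5, w = 20,
                      template_id = "template") {
  cfg <- list(variant = match.arg(variant),
              statistic = match.arg(statistic),
              gc_correct = isTRUE(gc_correct), nbins = nbins,
              z_min = z_min, min_seg = min_seg, w = w,
              template_id = template_id)
  class(cfg) <- "vn_config"
  cfg
}

## shared tail of both pipelines: per-sample raw CN, optional GC correction,
## final segmentation, and segmented-SD QC
.per_sample_cn <- function(test, ref_intensity, map, mask, config) {
  samples <- names(test)[-1]
  res <- purrr::map(samples, function(sm) {
    prof <- raw_cn(test[[sm]], ref_intensity, map, label = sm)
    prof$value[!mask] <- NA_real_
    if (config$gc_correct) {
      gcm <- fit_gc_wave(prof, nbins = config$nbins)
      prof <- apply_gc_correction(prof, gcm)
    }
    segs <- segment_profile(prof, z_min = config$z_min,
                            min_seg = config$min_seg, sample = sm)
    list(profile = prof, segments = segs,
         sd = segmented_sd(prof, segs))
  })
  raw <- purrr::map2(res, samples, function(r, sm) {
    dplyr::mutate(r$profile, sample = sm, .before = 1)
  }) |> dplyr::bind_rows()
  segs <- dplyr::bind_rows(purrr::map(res, "segments"))
  qc <- tibble::tibble(sample = samples,
                       segmented_sd = purrr::map_dbl(res, "sd"),
                       snr_cn3 = snr_cn3(purrr::map_dbl(res, "sd")))
  list(raw_cn = raw, segments = new_segments(segs), qc = qc)
}

#' Run the virtual-normal pipeline
#'
#' End-to-end construction of the virtual reference and per-sample raw copy
#' number: set averages (median by default), average log2 ratio, GC-wave
#' correction, baseline-shift estimation `S(p)` by mean-preserving
#' segmentation or Gaussian filtering, virtual reference
#' \eqn{I^{vn} = I^t_{avg} 2^{-S}}, then per-sample
#' \eqn{rawCN_i = \log_2(I_i / I^{vn})} with GC correction and final
#' segmentation.  Deterministic given inputs and configuration.
#'
#' @param test,template Intensity tibbles (`marker_id` + sample columns) on
#'   the same marker map; the test set needs at least 3 samples.
#' @param map A validated marker map.
#' @param config A [vn_config()].
#' @return A `vn_fit` list: `reference` (the `vn_reference`), `cn_avg`
#'   (corrected average ratio profile), `s` (the baseline-shift
#'   `vn_segments`), `raw_cn` (long tibble: `sample`, `marker_id`, `chrom`,
#'   `pos`, `gc`, `value`), `segments` (per-sample `vn_segments`), `qc`
#'   (per-sample segmented SD and S/N), `mask`, `config`.
#' @export
run_vn <- function(test, template, map, config = vn_config()) {
  map <- validate_marker_map(map)
  test <- validate_intensity_matrix(test, map)
  template <- validate_intensity_matrix(template, map)
  if (ncol(test) - 1L < 3L) {
    abort(paste("virtual-normal construction needs >= 3 test samples;",
                "use a conventional reference for smaller sets"))
  }
  mask <- validate_alignment(test, template)

  t_avg <- average_intensity(test, config$statistic)$intensity
  r_avg <- average_intensity(template, config$statistic)$intensity
  t_avg[!mask] <- NA_real_
  cn_avg <- cn_average(t_avg, r_avg, map, mask = mask)
  if (config$gc_correct) {
    gcm <- fit_gc_wave(cn_avg, nbins = config$nbins)
    cn_avg <- apply_gc_correction(cn_avg, gcm)
  } else {
    gcm <- NULL
  }
  s <- if (config$variant == "segmentation") {
    segment_profile(cn_avg, z_min = config$z_min, min_seg = config$min_seg,
                    sample = "CNavg")
  } else {
    smooth_profile(cn_avg, w = config$w, sample = "CNavg")
  }
  reference <- build_virtual_reference(
    t_avg, s, map,
    meta = list(template_id = config$template_id, variant = config$variant,
                statistic = config$statistic, gc_correct = config$gc_correct,
                z_min = config$z_min, min_seg = config$min_seg, w = config$w))

  per <- .per_sample_cn(test, reference, map, mask, config)
  fit <- list(reference = reference, cn_avg = cn_avg, s = s,
              raw_cn = per$raw_cn, segments = per$segments, qc = per$qc,
              gc_model = gcm, mask = mask, config = config, map = map)
  class(fit) <- "vn_fit"
  fit
}

#' Run the conventional pipeline against a fixed reference intensity
#'
#' The same per-sample tail as [run_vn()] (raw CN, optional GC correction,
#' segmentation, QC) but with any externally supplied reference intensity —
#' e.g. the template-set average (standard unpaired analysis), the uncorrected
#' test-set average, or a paired normal.  Used to compare reference choices.
#'
#' @param test Intensity tibble (`marker_id` + sample columns).
#' @param reference_intensity Numeric vector (or tibble with `intensity`) of
#'   per-marker reference intensities.
#' @param map A validated marker map.
#' @param config A [vn_config()] (its variant field is ignored; only the
#'   per-sample stages apply).
#' @return A `vn_fit`-like list with `raw_cn`, `segments`, `qc`, `mask`.
#' @export
run_reference <- function(test, reference_intensity, map,
                          config = vn_config()) {
  map <- validate_marker_map(map)
  test <- validate_intensity_matrix(test, map)
  ref <- if (is.data.frame(reference_intensity)) {
    reference_intensity$intensity
  } else {
    reference_intensity
  }
  stopifnot(length(ref) == nrow(map))
  mask <- intensity_mask(test) & is.finite(ref) & ref > 0
  ref_masked <- ref
  ref_masked[!mask] <- NA_real_
  per <- .per_sample_cn(test, ref_masked, map, mask, config)
  structure(list(raw_cn = per$raw_cn, segments = per$segments, qc = per$qc,
                 mask = mask, config = config, map = map),
            class = "vn_refrun")
}
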