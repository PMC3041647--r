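#' Validate a marker map
#'
#' A marker map is the genomic scaffold every signal in the package lives on:
#' one row per array marker with its chromosome, 1-based position and local GC
#' fraction.  Chromosome order is the order of first appearance in the table;
#' within a chromosome markers must be strictly sorted by position with no
#' duplicated (chromosome, position) pairs.
#'
#' @param map A data frame with columns `marker_id`, `chrom`, `pos`, `gc`.
#' @return A tibble with the validated columns, invisibly classed so that
#'   downstream functions can rely on the invariants.
#' @export
validate_marker_map <- function(map) {
  req <- c("marker_id", "chrom", "pos", "gc")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols) > 0) {
    abort(paste0("marker map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  map <- tibble::as_tibble(map)[req]
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$gc <- as.numeric(map$gc)

  if (anyNA(map$pos) || any(map$pos < 1L)) {
    abort("marker positions must be integers >= 1")
  }
  if (anyNA(map$gc) || any(map$gc < 0 | map$gc > 1)) {
    abort("gc fractions must lie in [0, 1]")
  }
  if (anyDuplicated(map$marker_id)) {
    abort("duplicated marker_id in marker map")
  }
  # chromosomes must appear in contiguous runs (order of first appearance)
  r <- rle(map$chrom)
  if (anyDuplicated(r$values)) {
    abort(paste0("chromosome '", r$values[duplicated(r$values)][1],
                 "' appears in non-contiguous blocks; map must be sorted"))
  }
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort(paste0("positions not strictly increasing on chromosome '",
                 bad$chrom[!bad$ok][1], "'"))
  }
  map
}

#' Chromosome order of a marker map
#'
#' @param map A validated marker map.
#' @return Character vector of chromosome labels in scaffold order.
#' @export
chrom_levels <- function(map) unique(as.character(map$chrom))

#' Validate an intensity matrix against a marker map
#'
#' An intensity table holds preprocessed total intensities (linear scale) with
#' one row per marker, first column `marker_id`, and one column per sample.
#' Row order must match the marker map exactly.
#'
#' @param x A data frame: `marker_id` plus one numeric column per sample.
#' @param map A validated marker map with identical marker ids and order.
#' @return The intensity tibble.
#' @export
validate_intensity_matrix <- function(x, map) {
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "marker_id") {
    abort("first column of an intensity matrix must be 'marker_id'")
  }
  if (ncol(x) < 2) abort("intensity matrix has no sample columns")
  if (nrow(x) != nrow(map)) {
    abort(sprintf("intensity matrix has %d rows but marker map has %d",
                  nrow(x), nrow(map)))
  }
  mism <- which(as.character(x$marker_id) != map$marker_id)
  if (length(mism) > 0) {
    abort(sprintf("marker id mismatch at row %d: '%s' vs map '%s'",
                  mism[1], x$marker_id[mism[1]], map$marker_id[mism[1]]))
  }
  for (nm in names(x)[-1]) x[[nm]] <- as.numeric(x[[nm]])
  x
}

#' Per-marker usability mask of an intensity matrix
#'
#' A marker is usable only if its intensity is finite and strictly positive in
#' every sample of the set; a failure in any one sample masks the marker
#' set-wide, so that averages and ratios stay defined on a single scaffold.
#'
#' @param x An intensity tibble (`marker_id` + sample columns).
#' @return Logical vector, one element per marker, `TRUE` = usable.
#' @export
intensity_mask <- function(x) {
  vals <- as.matrix(x[, -1, drop = FALSE])
  rowSums(!is.finite(vals) | vals <= 0) == 0
}

#' Align a test and a template intensity set on one scaffold
#'
#' Checks that both sets are defined on the same marker map (same ids, same
#' order) and returns the shared usability mask: markers usable in both sets.
#'
#' @param test,template Intensity tibbles with a `marker_id` first column.
#' @return Logical shared mask (length = number of markers).
#' @export
validate_alignment <- function(test, template) {
  if (nrow(test) != nrow(template)) {
    abort(sprintf("marker count mismatch: test has %d markers, template %d",
                  nrow(test), nrow(template)))
  }
  mism <- which(as.character(test$marker_id) !=
                  as.character(template$marker_id))
  if (length(mism) > 0) {
    abort(sprintf("marker id mismatch at row %d: test '%s' vs template '%s'",
                  mism[1], test$marker_id[mism[1]],
                  template$marker_id[mism[1]]))
  }
  intensity_mask(test) & intensity_mask(template)
}

#' Build a per-marker log2-ratio profile on a marker map
#'
#' @param map A validated marker map.
#' @param value Numeric vector of log2 values, one per marker (NA = masked).
#' @param label Provenance label stored as an attribute.
#' @return A tibble `marker_id, chrom, pos, gc, value`.
#' @export
cn_profile <- function(map, value, label = NULL) {
  stopifnot(length(value) == nrow(map))
  out <- tibble::tibble(marker_id = map$marker_id, chrom = map$chrom,
                        pos = map$pos, gc = map$gc,
                        value = as.numeric(value))
  attr(out, "label") <- label
  out
}
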