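#' Read a marker map from a tab-separated file
#'
#' Expected columns: `marker_id`, `chrom`, `pos`, `gc` (header required).
#'
#' @param path File path.
#' @return A validated marker-map tibble.
#' @export
read_marker_map <- function(path) {
  # gc is re-parsed with strtod (correctly rounded) so written maps
  # round-trip bit-exactly
  map <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           marker_id = readr::col_character(),
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           gc = readr::col_character()))
  map$gc <- as.numeric(map$gc)
  validate_marker_map(map)
}

#' Read an intensity matrix from a tab-separated file
#'
#' First column `marker_id`, remaining columns one per sample; the header row
#' carries the sample ids.
#'
#' @param path File path.
#' @return A tibble, `marker_id` plus numeric sample columns.
#' @export
read_intensity_matrix <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  x$marker_id <- as.character(x$marker_id)
  for (nm in names(x)[-1]) x[[nm]] <- as.numeric(x[[nm]])
  tibble::as_tibble(x)
}

#' Write a tab-separated table with an optional provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Character vector of header lines (written as `#` comments)
#'   or `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  # shortest decimal representation that round-trips doubles bit-exactly
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(function(v) is.double(v) && !is.integer(v)),
    .fmt_shortest))
  readr::write_tsv(x, con)
  invisible(path)
}

.fmt_shortest <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- !is.na(x) & as.numeric(out) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out[is.na(x)] <- NA_character_
  out
}

.provenance <- function(extra = character()) {
  c(paste0("vncn ", as.character(packageVersion("vncn"))), extra)
}

#' Write segments in SEG format
#'
#' Tab-separated, viewer-compatible columns `ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`; coordinates 1-based inclusive.
#'
#' @param segments A segment tibble (`sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `level`).
#' @param path Output path.
#' @param provenance Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, provenance = .provenance()) {
  seg <- tibble::tibble(
    ID = if ("sample" %in% names(segments)) segments$sample else "sample",
    chrom = segments$chrom,
    loc.start = segments$start,
    loc.end = segments$end,
    num.mark = segments$n_markers,
    seg.mean = segments$level)
  write_tsv_provenance(seg, path, provenance)
}

#' Write called segments in BED format
#'
#' Only segments whose |level| exceeds `threshold` are written.  BED uses
#' 0-based half-open coordinates; `name` is `gain`/`loss` by the sign of the
#' level and `score` is `|level| * 1000` capped at 1000.
#'
#' @param segments A segment tibble.
#' @param path Output path.
#' @param threshold Absolute log2 call threshold (default 0.2).
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path, threshold = 0.2) {
  calls <- segments[abs(segments$level) > threshold, , drop = FALSE]
  bed <- tibble::tibble(
    chrom = calls$chrom,
    chromStart = calls$start - 1L,
    chromEnd = calls$end,
    name = ifelse(calls$level > 0, "gain", "loss"),
    score = pmin(1000L, as.integer(round(abs(calls$level) * 1000))),
    strand = ".")
  con <- file(path, open = "wb")
  on.exit(close(con))
  readr::write_tsv(bed, con, col_names = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param qc A list or data frame of QC quantities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize / read a fitted GC-wave model
#'
#' Small tabular format: `bin_low`, `bin_high`, `n`, `level` (log2).
#'
#' @param model A `vn_gc_model`.
#' @param path File path.
#' @return `write_gc_model()` returns `path`; `read_gc_model()` the model.
#' @export
write_gc_model <- function(model, path) {
  write_tsv_provenance(tibble::as_tibble(unclass(model)), path, .provenance())
}

#' @rdname write_gc_model
#' @export
read_gc_model <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  new_gc_model(x)
}
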