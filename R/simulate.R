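#' Simulation configuration for synthetic SNP-array intensities
#'
#' Describes the generative model the virtual-normal method exploits: per-set
#' shared probe-effect tracks (the high-frequency component common to all
#' samples processed under one protocol/batch), private per-sample noise,
#' a GC wave, and copy-number events carried by a configurable fraction of
#' test samples.  All noise is Gaussian in the log2 domain (lognormal
#' intensities), so closed-form SD predictions are available downstream.
#'
#' The defaults mirror the regime the method targets: 20 FFPE-like test
#' samples against 10 template normals from a different protocol, shared
#' probe-effect SD 0.3 per set (independent tracks, modelling the
#' FFPE-vs-frozen mismatch) and private per-sample noise SD 0.1.
#'
#' @param n_markers Total markers (default 10000).
#' @param n_chrom Number of equally sized chromosomes (default 1).
#' @param n_test,n_template Sample counts (defaults 20 and 10).
#' @param shared_sd_test,shared_sd_template SD (log2) of the marker-indexed
#'   probe-effect track shared within each set (defaults 0.3).
#' @param template_shares_test_track If `TRUE` the template set reuses the
#'   test set's shared track — the paired / same-batch scenario.
#' @param private_sd Per-sample, per-marker noise SD in log2 (default 0.1).
#' @param gc_slope Amplitude of the GC wave: the log2 wave is
#'   `gc_slope * (gc - mean(gc))` (default 0, no wave).
#' @param base Baseline intensity (linear scale, default 2000).
#' @param cna Data frame of events: `chrom`, `start` (marker index within the
#'   chromosome), `length` (markers), `amplitude` (log2), `carrier_frac`
#'   (fraction of test samples carrying the event; carriers are drawn without
#'   replacement, count rounded to nearest integer).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 10000, n_chrom = 1,
                       n_test = 20, n_template = 10,
                       shared_sd_test = 0.3, shared_sd_template = 0.3,
                       template_shares_test_track = FALSE,
                       private_sd = 0.1, gc_slope = 0, base = 2000,
                       cna = NULL, seed = 1) {
  stopifnot(shared_sd_test >= 0, shared_sd_template >= 0, private_sd >= 0,
            n_markers >= n_chrom, n_test >= 1, n_template >= 1)
  if (is.null(cna)) {
    cna <- tibble::tibble(chrom = character(), start = integer(),
                          length = integer(), amplitude = numeric(),
                          carrier_frac = numeric())
  }
  cna <- tibble::as_tibble(cna)
  stopifnot(all(cna$carrier_frac >= 0 & cna$carrier_frac <= 1))
  cfg <- list(n_markers = n_markers, n_chrom = n_chrom, n_test = n_test,
              n_template = n_template, shared_sd_test = shared_sd_test,
              shared_sd_template = shared_sd_template,
              template_shares_test_track =
                isTRUE(template_shares_test_track),
              private_sd = private_sd, gc_slope = gc_slope, base = base,
              cna = cna, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## deterministic substream seeds so that e.g. changing the template sample
## count never perturbs test-set draws
.stream_seeds <- function(seed, n = 6) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a test + template SNP-array intensity study with ground truth
#'
#' Generates, per marker `p` and sample `i`,
#' `intensity = base * 2^(shared(p) + private_i(p) + gcwave(gc(p)) + cna_i(p))`
#' where `shared` is the set's probe-effect track, `private_i` is sample
#' noise, and `cna_i` is the sample's true copy-number track (nonzero only
#' for carriers).  Test-set, template-set and carrier draws use independent
#' substreams of `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `map` (marker map), `test`, `template` (intensity
#'   tibbles), `truth` (list: `events` — per-sample true segments with marker
#'   and position coordinates; `shared_test`, `shared_template`, `gc_wave` —
#'   the generative tracks; `cna_tracks` — markers x test-samples matrix of
#'   true log2 CNA values).
#' @export
simulate_cn_study <- function(config = sim_config()) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  n <- cfg$n_markers
  seeds <- .stream_seeds(cfg$seed)

  per_chr <- diff(round(seq(0, n, length.out = cfg$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chr)
  within <- unlist(lapply(per_chr, seq_len), use.names = FALSE)

  set.seed(seeds[1])
  gc <- 0.45 + 0.12 * sin(2 * pi * within / 2000) + rnorm(n, sd = 0.03)
  gc <- pmin(pmax(gc, 0.2), 0.8)
  map <- tibble::tibble(marker_id = sprintf("SNP_%06d", seq_len(n)),
                        chrom = chrom, pos = within * 1000L, gc = gc)
  gc_wave <- cfg$gc_slope * (gc - mean(gc))

  set.seed(seeds[2])
  shared_test <- if (cfg$shared_sd_test > 0) {
    rnorm(n, sd = cfg$shared_sd_test)
  } else {
    numeric(n)
  }
  set.seed(seeds[3])
  shared_template <- if (cfg$template_shares_test_track) {
    shared_test
  } else if (cfg$shared_sd_template > 0) {
    rnorm(n, sd = cfg$shared_sd_template)
  } else {
    numeric(n)
  }

  # carriers and per-sample CNA tracks
  set.seed(seeds[4])
  cna_tracks <- matrix(0, nrow = n, ncol = cfg$n_test)
  events <- list()
  if (nrow(cfg$cna) > 0) {
    chr_offset <- setNames(cumsum(c(0, head(per_chr, -1))),
                           paste0("chr", seq_len(cfg$n_chrom)))
    for (k in seq_len(nrow(cfg$cna))) {
      ev <- cfg$cna[k, ]
      if (!ev$chrom %in% names(chr_offset)) {
        abort(sprintf("CNA event %d on unknown chromosome '%s'", k, ev$chrom))
      }
      len_chr <- per_chr[match(ev$chrom, names(chr_offset))]
      if (ev$start < 1 || ev$start + ev$length - 1 > len_chr) {
        abort(sprintf("CNA event %d exceeds bounds of %s", k, ev$chrom))
      }
      rows <- chr_offset[[ev$chrom]] + ev$start:(ev$start + ev$length - 1)
      n_car <- round(ev$carrier_frac * cfg$n_test)
      carriers <- if (n_car > 0) sort(sample.int(cfg$n_test, n_car)) else integer(0)
      cna_tracks[rows, carriers] <- cna_tracks[rows, carriers] + ev$amplitude
      if (length(carriers) > 0) {
        events[[k]] <- tibble::tibble(
          sample = sprintf("T%02d", carriers), chrom = ev$chrom,
          start_marker = ev$start,
          end_marker = ev$start + ev$length - 1L,
          start = map$pos[rows[1]], end = map$pos[rows[length(rows)]],
          n_markers = as.integer(ev$length), amplitude = ev$amplitude)
      }
    }
  }
  truth_events <- dplyr::bind_rows(events)

  log2_base <- log2(cfg$base)
  set.seed(seeds[5])
  test_vals <- vapply(seq_len(cfg$n_test), function(i) {
    eps <- if (cfg$private_sd > 0) rnorm(n, sd = cfg$private_sd) else numeric(n)
    2^(log2_base + shared_test + eps + gc_wave + cna_tracks[, i])
  }, numeric(n))
  colnames(test_vals) <- sprintf("T%02d", seq_len(cfg$n_test))

  set.seed(seeds[6])
  template_vals <- vapply(seq_len(cfg$n_template), function(j) {
    eps <- if (cfg$private_sd > 0) rnorm(n, sd = cfg$private_sd) else numeric(n)
    2^(log2_base + shared_template + eps + gc_wave)
  }, numeric(n))
  colnames(template_vals) <- sprintf("N%02d", seq_len(cfg$n_template))

  list(map = validate_marker_map(map),
       test = dplyr::bind_cols(tibble::tibble(marker_id = map$marker_id),
                               tibble::as_tibble(test_vals)),
       template = dplyr::bind_cols(tibble::tibble(marker_id = map$marker_id),
                                   tibble::as_tibble(template_vals)),
       truth = list(events = truth_events, shared_test = shared_test,
                    shared_template = shared_template, gc_wave = gc_wave,
                    cna_tracks = cna_tracks, config = cfg))
}

#' Score called segments against simulation truth
#'
#' Calls are segments whose |level| exceeds `threshold`; each call is matched
#' to a same-sample truth event when their marker spans overlap reciprocally
#' by at least `min_overlap`.  Unmatched calls are false positives, unmatched
#' truth events false negatives.
#'
#' @param segments A `vn_segments` tibble (with `sample` labels matching the
#'   simulator's `T01`, `T02`, ...).
#' @param truth The `truth` element of [simulate_cn_study()] output.
#' @param map The marker map the segments live on.
#' @param threshold Absolute log2 call threshold (default 0.2).
#' @param min_overlap Reciprocal-overlap fraction for a match (default 0.5).
#' @return A list: `n_fp`, `n_fn`, `n_matched`, `breakpoint_error` (mean
#'   absolute marker error over matched starts/ends), `amplitude_error`
#'   (mean absolute level error of matches), and the matched-call tibble.
#' @export
score_against_truth <- function(segments, truth, map, threshold = 0.2,
                                min_overlap = 0.5) {
  calls <- segments[abs(segments$level) > threshold, , drop = FALSE]
  tr <- truth$events
  if (nrow(tr) == 0) {
    return(list(n_fp = nrow(calls), n_fn = 0L, n_matched = 0L,
                breakpoint_error = NA_real_, amplitude_error = NA_real_,
                matches = tibble::tibble()))
  }
  # marker-index span of each call within its chromosome
  call_span <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
      rows <- which(map$chrom == d$chrom[i])
      c(match(TRUE, map$pos[rows] >= d$start[i]),
        length(rows) - match(TRUE, rev(map$pos[rows] <= d$end[i])) + 1L)
    }, integer(2))
  }
  matched_tr <- rep(FALSE, nrow(tr))
  matched_call <- rep(FALSE, nrow(calls))
  rows_match <- list()
  if (nrow(calls) > 0) {
    sp <- call_span(calls)
    for (i in seq_len(nrow(calls))) {
      cand <- which(!matched_tr & tr$sample == calls$sample[i] &
                      tr$chrom == calls$chrom[i])
      for (j in cand) {
        ov <- min(sp[2, i], tr$end_marker[j]) -
          max(sp[1, i], tr$start_marker[j]) + 1
        if (ov <= 0) next
        len_c <- sp[2, i] - sp[1, i] + 1
        len_t <- tr$end_marker[j] - tr$start_marker[j] + 1
        if (ov / len_c >= min_overlap && ov / len_t >= min_overlap) {
          matched_tr[j] <- TRUE
          matched_call[i] <- TRUE
          rows_match[[length(rows_match) + 1]] <- tibble::tibble(
            sample = calls$sample[i], chrom = calls$chrom[i],
            bp_err = (abs(sp[1, i] - tr$start_marker[j]) +
                        abs(sp[2, i] - tr$end_marker[j])) / 2,
            amp_err = abs(calls$level[i] - tr$amplitude[j]))
          break
        }
      }
    }
  }
  matches <- dplyr::bind_rows(rows_match)
  list(n_fp = sum(!matched_call), n_fn = sum(!matched_tr),
       n_matched = sum(matched_call),
       breakpoint_error = if (nrow(matches)) mean(matches$bp_err) else NA_real_,
       amplitude_error = if (nrow(matches)) mean(matches$amp_err) else NA_real_,
       matches = matches)
}
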