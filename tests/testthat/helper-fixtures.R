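# Shared fixtures and independent oracles for the test suite.

# flat marker map with evenly spaced markers and controllable gc
make_map <- function(n, n_chrom = 1, gc = rep(0.5, n)) {
  per <- diff(round(seq(0, n, length.out = n_chrom + 1)))
  validate_marker_map(tibble::tibble(
    marker_id = sprintf("m%05d", seq_len(n)),
    chrom = rep(paste0("chr", seq_len(n_chrom)), per),
    pos = unlist(lapply(per, seq_len)) * 1000L,
    gc = gc))
}

make_profile <- function(values, map = make_map(length(values))) {
  cn_profile(map, values)
}

# intensity tibble from a markers x samples matrix of log2 signals
intensity_from_log2 <- function(log2_mat, map, base = 2000,
                                prefix = "S") {
  m <- 2^(log2(base) + log2_mat)
  colnames(m) <- sprintf("%s%02d", prefix, seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(marker_id = map$marker_id),
                   tibble::as_tibble(m))
}

# one flat segment per chromosome at a fixed level, as a vn_segments table
new_segments_for_test <- function(map, level = 0) {
  seg <- map |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(start = min(pos), end = max(pos),
                     n_markers = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sample = "fixture", level = level, .before = 1)
  vncn:::new_segments(seg)
}

# ---- segmentation oracles ------------------------------------------------

# same z statistic as the implementation, but by exhaustive search over every
# single-breakpoint candidate
brute_force_single_split <- function(x, min_seg, sigma) {
  n <- length(x)
  k <- min_seg:(n - min_seg)
  z <- vapply(k, function(kk) {
    abs(mean(x[1:kk]) - mean(x[(kk + 1):n])) /
      (sigma * sqrt(1 / kk + 1 / (n - kk)))
  }, numeric(1))
  list(k = k[which.max(z)], z = max(z))
}

# exhaustive dynamic-programming segmentation: minimum RSS for exactly k
# segments respecting a minimum segment length; returns breakpoints (last
# index of each segment but the final one)
dp_segment_k <- function(x, k, min_seg) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_rss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # cost[k_, j]: min RSS of x[1..j] in k_ segments
  cost <- matrix(Inf, k, n)
  back <- matrix(NA_integer_, k, n)
  for (j in min_seg:n) cost[1, j] <- seg_rss(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in (kk * min_seg):n) {
        cand <- ((kk - 1) * min_seg):(j - min_seg)
        v <- cost[kk - 1, cand] + vapply(cand + 1, seg_rss, numeric(1),
                                         j = j)
        cost[kk, j] <- min(v)
        back[kk, j] <- cand[which.min(v)]
      }
    }
  }
  bps <- integer(0)
  j <- n
  kk <- k
  while (kk > 1) {
    bps <- c(back[kk, j], bps)
    j <- back[kk, j]
    kk <- kk - 1
  }
  list(breakpoints = bps, rss = cost[k, n])
}

# model selection mirroring the recursive criterion: the largest k (<= kmax)
# whose RSS-optimal segmentation has every adjacent-segment contrast at
# z >= z_min
dp_oracle <- function(x, z_min, min_seg, kmax = 3,
                      sigma = vncn:::.noise_sigma(x)) {
  if (sigma <= 0) return(integer(0))
  best <- integer(0)
  for (k in 2:kmax) {
    if (length(x) < k * min_seg) break
    fit <- dp_segment_k(x, k, min_seg)
    bounds <- c(0, fit$breakpoints, length(x))
    z <- vapply(seq_len(k - 1), function(i) {
      l <- (bounds[i] + 1):bounds[i + 1]
      r <- (bounds[i + 1] + 1):bounds[i + 2]
      abs(mean(x[l]) - mean(x[r])) /
        (sigma * sqrt(1 / length(l) + 1 / length(r)))
    }, numeric(1))
    if (all(z >= z_min)) best <- fit$breakpoints else break
  }
  best
}

# mean of a sample's raw CN (or its segment levels) over a truth event span
event_mean <- function(fit, sample, map, chrom, start_marker, end_marker,
                       from = c("raw", "segments")) {
  from <- match.arg(from)
  rows <- which(map$chrom == chrom)[start_marker:end_marker]
  if (from == "raw") {
    d <- fit$raw_cn[fit$raw_cn$sample == sample, ]
    mean(d$value[rows], na.rm = TRUE)
  } else {
    seg <- fit$segments[fit$segments$sample == sample, ]
    mean(eval_segments(seg, map)[rows], na.rm = TRUE)
  }
}
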