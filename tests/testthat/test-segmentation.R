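test_that("constant input yields one mean-level segment per chromosome", {
  map <- make_map(60, n_chrom = 3)
  s <- segment_profile(make_profile(rep(0.25, 60), map))
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$level), 0.25)
  expect_equal(s$n_markers, rep(20L, 3))
})

test_that("a clear step is found where exhaustive single-split search puts it", {
  withr::local_seed(21)
  for (rep in 1:10) {
    x <- c(rnorm(50, 0, 0.1), rnorm(50, 0.6, 0.1))
    prof <- make_profile(x)
    s <- segment_profile(prof, z_min = 5, min_seg = 5)
    expect_equal(nrow(s), 2)
    # breakpoint within +/- 2 markers of the true step at index 51
    expect_lte(abs(s$n_markers[1] - 50), 2)
    # and it matches the brute-force argmax of the same statistic
    oracle <- brute_force_single_split(x, 5, vncn:::.noise_sigma(x))
    expect_equal(s$n_markers[1], oracle$k)
  }
})

test_that("segment levels equal within-segment means exactly", {
  withr::local_seed(22)
  x <- c(rnorm(80, 0, 0.2), rnorm(70, 1, 0.2), rnorm(50, -0.5, 0.2))
  prof <- make_profile(x)
  s <- segment_profile(prof, z_min = 4)
  v <- eval_segments(s, prof)
  for (i in seq_len(nrow(s))) {
    sel <- prof$pos >= s$start[i] & prof$pos <= s$end[i]
    expect_equal(s$level[i], mean(x[sel]), tolerance = 1e-12)
  }
  # every unmasked marker is covered by exactly one segment
  expect_true(all(is.finite(v)))
  expect_equal(sum(s$n_markers), length(x))
})

test_that("recursive segmentation agrees with the DP oracle on small instances", {
  withr::local_seed(23)
  n_rep <- 60
  agree <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 200
    n_bp <- sample(0:2, 1)
    bounds <- sort(sample(20:180, n_bp))
    levels <- cumsum(c(0, sample(c(-0.6, 0.6), n_bp, replace = TRUE)))
    truth <- rep(levels, diff(c(0, bounds, n)))
    x <- truth + rnorm(n, sd = 0.1)
    got <- segment_profile(make_profile(x), z_min = 5, min_seg = 5)
    got_bp <- cumsum(got$n_markers)
    got_bp <- got_bp[-length(got_bp)]
    want_bp <- dp_oracle(x, z_min = 5, min_seg = 5)
    agree[r] <- length(got_bp) == length(want_bp) &&
      (length(got_bp) == 0 || all(abs(got_bp - want_bp) <= 2))
  }
  expect_gte(mean(agree), 0.95)
})

test_that("raising z_min never increases the number of segments", {
  withr::local_seed(24)
  x <- c(rnorm(60, 0, 0.15), rnorm(40, 0.4, 0.15), rnorm(60, -0.2, 0.15),
         rnorm(40, 0.3, 0.15))
  prof <- make_profile(x)
  counts <- vapply(c(2, 3, 4, 6, 10, 20),
                   function(z) nrow(segment_profile(prof, z_min = z)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Gaussian smoothing is exact on constants and normalizes weights", {
  map <- make_map(100)
  s <- smooth_profile(make_profile(rep(0.7, 100), map), w = 20)
  expect_equal(s$level, rep(0.7, 100))
  expect_equal(s$n_markers, rep(1L, 100))

  # unit impulse: smoothed output sums to 1 over the window support
  imp <- rep(0, 100)
  imp[50] <- 1
  si <- smooth_profile(make_profile(imp, map), w = 20)
  expect_equal(sum(si$level), 1, tolerance = 1e-12)

  # chromosome shorter than 3 markers passes through unchanged
  map2 <- make_map(2)
  s2 <- smooth_profile(cn_profile(map2, c(0.1, 0.9)), w = 20)
  expect_equal(s2$level, c(0.1, 0.9))
})

test_that("smoothed step crosses half-amplitude at the step location", {
  n <- 200
  x <- c(rep(0, 100), rep(1, 100))
  s <- smooth_profile(make_profile(x), w = 20)
  # closed-form oracle: renormalized truncated-Gaussian convolution
  w <- 20
  h <- floor(w / 2)
  k <- dnorm(-h:h, sd = w / 4)
  k <- k / sum(k)
  oracle <- vapply(seq_len(n), function(i) {
    j <- pmax(1, i - h):pmin(n, i + h)
    kk <- k[j - i + h + 1]
    sum(kk * x[j]) / sum(kk)
  }, numeric(1))
  expect_equal(s$level, oracle, tolerance = 1e-12)
  crossing <- which(s$level >= 0.5)[1]
  expect_lte(abs(crossing - 101), 1)

  # genome-wide mean is preserved up to edge effects
  expect_equal(mean(s$level), mean(x), tolerance = 0.01)
})

test_that("masked markers are skipped and all-masked chromosomes dropped", {
  map <- make_map(40, n_chrom = 2)
  x <- rep(0.3, 40)
  x[21:40] <- NA                        # chr2 fully masked
  x[5] <- NA
  s <- segment_profile(cn_profile(map, x))
  expect_equal(unique(s$chrom), "chr1")
  expect_equal(sum(s$n_markers), 19)
})
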