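test_that("set averages follow the configured statistic per marker", {
  map <- make_map(3)
  x <- tibble::tibble(marker_id = map$marker_id,
                      A = c(2, 1, 1), B = c(4, 2, 2), C = c(6, 3, 3),
                      D = c(5, 100, 4))
  expect_equal(average_intensity(x[1:4])$intensity[1], 4)   # median{2,4,6}
  expect_equal(average_intensity(x)$intensity[2], 2.5)      # {1,2,3,100}
  one <- average_intensity(x[, 1:2])
  expect_equal(one$intensity, x$A)                          # single sample
  expect_equal(average_intensity(x, "mean")$intensity[3], mean(c(1, 2, 3, 4)))
  expect_error(average_intensity(x[, 1, drop = FALSE]), "no sample")
})

test_that("the average log2 ratio matches its defining values", {
  map <- make_map(3)
  prof <- cn_average(c(4, 2, 1), c(2, 2, 4), map)
  expect_equal(prof$value, c(1, 0, -2))
})

test_that("virtual reference satisfies its algebraic identities", {
  withr::local_seed(31)
  map <- make_map(200)
  t_avg <- 2^(log2(1000) + rnorm(200, sd = 0.2))

  # S == 0 is the identity transform
  s0 <- new_segments_for_test(map, level = 0)
  ref0 <- build_virtual_reference(t_avg, s0, map)
  expect_equal(ref0$intensity, t_avg)

  # a one-unit shift halves the reference
  s1 <- new_segments_for_test(map, level = 1)
  expect_equal(build_virtual_reference(1000, s1, map)$intensity[1], 500)

  # exact wiring identity: log2(t_avg / I_vn) == S(p) everywhere
  x <- c(rep(0, 100), rep(0.58, 50), rep(0, 50))
  s <- segment_profile(cn_profile(map, x + rnorm(200, sd = 0.05)), z_min = 4)
  ref <- build_virtual_reference(t_avg, s, map)
  expect_equal(log2(t_avg / ref$intensity), eval_segments(s, map),
               tolerance = 1e-12)

  # raw CN against the reference itself is zero; doubling is +1
  expect_equal(raw_cn(ref$intensity, ref, map)$value, rep(0, 200))
  expect_equal(raw_cn(2 * ref$intensity, ref, map)$value, rep(1, 200))
})

test_that("null pipeline: no noise, no events gives flat zero raw CN", {
  sim <- simulate_cn_study(sim_config(
    n_markers = 600, n_chrom = 2, n_test = 5, n_template = 4,
    shared_sd_test = 0, shared_sd_template = 0, private_sd = 0, seed = 3))
  fit <- suppressWarnings(run_vn(sim$test, sim$template, sim$map,
                                 vn_config(gc_correct = FALSE)))
  expect_equal(max(abs(fit$raw_cn$value)), 0, tolerance = 1e-12)
  # one segment per chromosome and sample
  expect_equal(nrow(fit$segments), 2 * 5)
})

test_that("fewer than 3 test samples is refused", {
  sim <- simulate_cn_study(sim_config(n_markers = 200, n_test = 2,
                                      n_template = 3, seed = 4))
  expect_error(run_vn(sim$test, sim$template, sim$map), ">= 3 test samples")
})

test_that("a common amplification is suppressed by the naive test-average
           reference but restored by the virtual normal", {
  sim <- simulate_cn_study(sim_config(
    n_markers = 2500, n_chrom = 1, n_test = 20, n_template = 10,
    shared_sd_test = 0, shared_sd_template = 0, private_sd = 0.1,
    cna = tibble::tibble(chrom = "chr1", start = 1100, length = 100,
                         amplitude = 0.58, carrier_frac = 1),
    seed = 5))
  samples <- sprintf("T%02d", 1:20)

  naive <- run_reference(sim$test, average_intensity(sim$test), sim$map,
                         vn_config(gc_correct = FALSE))
  rec_naive <- vapply(samples, function(sm) {
    event_mean(naive, sm, sim$map, "chr1", 1100, 1199, from = "segments")
  }, numeric(1))
  expect_true(all(abs(rec_naive) < 0.1))

  fit <- run_vn(sim$test, sim$template, sim$map, vn_config())
  rec_vn <- vapply(samples, function(sm) {
    event_mean(fit, sm, sim$map, "chr1", 1100, 1199, from = "segments")
  }, numeric(1))
  expect_true(all(abs(rec_vn - 0.58) < 0.05))

  # reference property (b): the corrected reference carries no residual
  # segment beyond +/- 0.2 when re-segmented against the template average
  r_avg <- average_intensity(sim$template)$intensity
  resid <- cn_profile(sim$map, log2(fit$reference$intensity / r_avg))
  reseg <- segment_profile(resid, z_min = 4)
  expect_true(all(abs(reseg$level) < 0.2))
})

test_that("virtual reference keeps the shared probe-effect track (property a)", {
  sim <- simulate_cn_study(sim_config(
    n_markers = 3000, n_chrom = 1, n_test = 15, n_template = 10,
    shared_sd_test = 0.3, shared_sd_template = 0.3, private_sd = 0.1,
    seed = 6))
  fit <- run_vn(sim$test, sim$template, sim$map, vn_config())
  hf <- function(v) {
    sm <- smooth_profile(cn_profile(sim$map, v), w = 30)$level
    v - sm
  }
  cor_vn <- cor(hf(log2(fit$reference$intensity)), sim$truth$shared_test)
  cor_tm <- cor(hf(log2(average_intensity(sim$template)$intensity)),
                sim$truth$shared_test)
  expect_gt(cor_vn, cor_tm)
  expect_gt(cor_vn, 0.9)
})

test_that("VN cuts raw CN noise below the mismatched-template reference", {
  reps <- 5
  for (r in seq_len(reps)) {
    sim <- simulate_cn_study(sim_config(
      n_markers = 1500, n_chrom = 1, n_test = 10, n_template = 8,
      shared_sd_test = 0.3, shared_sd_template = 0.3, private_sd = 0.1,
      seed = 100 + r))
    cfgv <- vn_config(gc_correct = FALSE)
    fit <- run_vn(sim$test, sim$template, sim$map, cfgv)
    tmpl <- run_reference(sim$test, average_intensity(sim$template),
                          sim$map, cfgv)
    expect_lt(mean(fit$qc$segmented_sd), mean(tmpl$qc$segmented_sd))
  }
})

test_that("VN noise is no worse than paired-normal processing when private
           noise dominates", {
  sim <- simulate_cn_study(sim_config(
    n_markers = 2000, n_chrom = 1, n_test = 10, n_template = 10,
    shared_sd_test = 0.3, template_shares_test_track = TRUE,
    private_sd = 0.1, seed = 8))
  cfg <- vn_config(gc_correct = FALSE)
  fit <- run_vn(sim$test, sim$template, sim$map, cfg)
  # paired analysis: each tumour against its own normal (same shared track)
  paired_sd <- vapply(1:10, function(i) {
    p <- raw_cn(sim$test[[i + 1]], sim$template[[i + 1]], sim$map)
    segmented_sd(p, segment_profile(p, z_min = 4))
  }, numeric(1))
  expect_lte(mean(fit$qc$segmented_sd), mean(paired_sd))
})

test_that("filter-variant VN keeps at least 70% of a minority event's
           amplitude for both averaging statistics", {
  for (stat in c("median", "mean")) {
    sim <- simulate_cn_study(sim_config(
      n_markers = 2000, n_chrom = 1, n_test = 20, n_template = 10,
      shared_sd_test = 0, shared_sd_template = 0, private_sd = 0.1,
      cna = tibble::tibble(chrom = "chr1", start = 900, length = 50,
                           amplitude = 0.58, carrier_frac = 0.25),
      seed = 9))
    carriers <- unique(sim$truth$events$sample)
    fit <- run_vn(sim$test, sim$template, sim$map,
                  vn_config(variant = "filter", statistic = stat, w = 20))
    rec <- vapply(carriers, function(sm) {
      event_mean(fit, sm, sim$map, "chr1", 900, 949, from = "raw")
    }, numeric(1))
    expect_true(all(rec >= (1 - 0.3) * 0.58))
  }
})

test_that("tidy, glance and autoplot work on a fit", {
  sim <- simulate_cn_study(sim_config(n_markers = 800, n_chrom = 2,
                                      n_test = 4, n_template = 3, seed = 10))
  fit <- run_vn(sim$test, sim$template, sim$map,
                vn_config(gc_correct = FALSE))
  td <- tidy(fit)
  expect_true(all(c("sample", "chrom", "level", "call") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_test, 4)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$reference), "ggplot")
  expect_output(print(fit), "Virtual-normal fit")
})
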