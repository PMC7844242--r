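test_that("global threshold is the (1-r) quantile of the fitted normal", {
  # a sample with exactly mean 100, sd 10 by construction
  x <- as.vector(scale(rnorm(500))) * 10 + 100
  expect_equal(estimate_global_threshold(x, r = pnorm(-3)), 130)
  expect_equal(estimate_global_threshold(x, sigma = 3), 130)
  expect_equal(estimate_global_threshold(x, r = 0.5), 100)   # median of fit
  set.seed(5)
  y <- rnorm(5000, 50, 4)
  thr <- estimate_global_threshold(y, r = pnorm(-2))
  expect_equal(thr, mean(y) + qnorm(1 - pnorm(-2)) * sd(y))   # inverse-CDF oracle
  expect_equal(thr, 58, tolerance = 0.5)
  expect_error(estimate_global_threshold(c(1), r = 0.1), "at least 2")
  expect_error(estimate_global_threshold(c(1, NaN), r = 0.1), "finite")
  expect_error(estimate_global_threshold(y, r = 0.7), "0, 0.5")
})

test_that("raising r strictly lowers the threshold (monotonicity)", {
  set.seed(6)
  x <- rnorm(2000, 80, 6)
  rs <- c(0.001, 0.01, 0.1, 0.3, 0.5)
  thrs <- vapply(rs, function(r) estimate_global_threshold(x, r = r), 0)
  expect_true(all(diff(thrs) < 0))
})

test_that("per-pixel dark level is the median across frames", {
  traces <- array(100L, c(2, 2, 100))
  traces[1, 1, 100] <- 500L                      # one electron in 100 frames
  st <- frame_stack(traces, bit_depth = 16)
  expect_equal(pixel_dark_levels(st)[1, 1], 100)

  st3 <- frame_stack(array(c(1L, 2L, 3L), c(1, 1, 3)), bit_depth = 4)
  expect_equal(pixel_dark_levels(st3)[1, 1], 2)

  set.seed(8)
  a <- array(sample(0:4000, 4 * 4 * 31, replace = TRUE), c(4, 4, 31))
  st31 <- frame_stack(a, bit_depth = 12)
  expect_equal(pixel_dark_levels(st31),
               apply(a, c(1, 2), function(t) sort(t)[16]))   # sorting oracle
  expect_equal(pixel_dark_levels(st31, method = "mean"), rowMeans(a, dims = 2))
  expect_warning(pixel_dark_levels(frame_stack(a[, , 1, drop = FALSE],
                                               bit_depth = 12)),
                 "single-frame")
})

test_that("pixel gain is the median of the N largest dark-subtracted values", {
  tr <- array(0L, c(1, 1, 5))
  tr[1, 1, ] <- c(0L, 0L, 0L, 50L, 60L)
  st <- frame_stack(tr, bit_depth = 8)
  expect_equal(pixel_gains(st, total_dose = 2, dark = matrix(0, 1, 1))[1, 1], 55)
  zero <- frame_stack(array(0L, c(2, 2, 4)), bit_depth = 8)
  expect_true(all(pixel_gains(zero, 1, dark = matrix(0, 2, 2)) == 0))
  expect_error(pixel_gains(st, total_dose = 5), "smaller than")
})

test_that("per-pixel thresholds shift with dark and scale with gain", {
  dark <- matrix(c(100, 105, 80, 100), 2, 2)
  gain <- matrix(c(1, 1, 2, -0.5), 2, 2)
  cf <- build_calibration_frame(global_threshold = 130, global_dark_mean = 100,
                                global_gain = 1, dark = dark, gain = gain)
  expect_equal(cf$threshold[1, 1], 130)     # matches global dark and gain
  expect_equal(cf$threshold[2, 1], 135)     # dark shifted by +5
  expect_equal(cf$threshold[1, 2], 80 + 30 * 2)   # doubled gain
  expect_identical(cf$threshold[2, 2], Inf)       # non-positive gain = dead
  expect_error(build_calibration_frame(130, 100, 0, dark, gain),
               "strictly positive")
})

test_that("common-mode offsets are removed block by block", {
  dark <- matrix(100, 8, 8)
  calib <- calibration_frame(dark + 12, dark = dark)
  frame <- dark
  frame[1:4, 1:8] <- frame[1:4, 1:8] + 7       # one 4 x 8 block offset
  out <- common_mode_correct(frame, calib, block_shape = c(4, 8))
  expect_equal(out, dark, ignore_attr = TRUE)
  expect_equal(common_mode_correct(matrix(0, 8, 8),
                                   calibration_frame(matrix(12, 8, 8)),
                                   c(4, 8)),
               matrix(0, 8, 8))
  set.seed(9)
  offsets <- runif(4, -5, 5)
  fr2 <- dark
  for (b in 1:4) fr2[, (2 * b - 1):(2 * b)] <- fr2[, (2 * b - 1):(2 * b)] + offsets[b]
  out2 <- common_mode_correct(fr2, calib, block_shape = c(8, 2))
  expect_equal(max(abs(out2 - dark)), 0, tolerance = 1e-9)
})

test_that("area filtering keeps puddles inside the area band", {
  m <- matrix(FALSE, 10, 10)
  m[1, 1] <- TRUE                              # area 1
  m[4, 4:5] <- TRUE                            # area 2
  m[7:9, 7:8] <- TRUE; m[6, 7] <- TRUE         # area 7
  ps <- label_components(m)
  expect_equal(sort(ps$area), c(1L, 2L, 7L))
  kept <- area_filter(ps, max_area = 6, min_area = 2)
  expect_equal(kept$n, 1L)
  expect_equal(kept$area, 2L)
  expect_equal(sum(kept$labels > 0), 2L)
  ident <- area_filter(ps, max_area = Inf, min_area = 1)
  expect_equal(ident$n, ps$n)
  expect_equal(ident$labels, ps$labels)
  set.seed(10)
  m2 <- rand_mask(30, 30, 0.3)
  ps2 <- label_components(m2)
  expect_equal(area_filter(ps2, 3, 2)$n, sum(ps2$area >= 2 & ps2$area <= 3))
  expect_error(area_filter(ps2, max_area = 1, min_area = 2), "max_area")
})

test_that("dose estimation counts puddles emanating from the patch centre", {
  # frame equals the patch: every random patch is centred at (6, 6)
  fr <- array(100L, c(11, 11, 40))
  fr[6, 6, 2] <- 220L; fr[6, 7, 2] <- 180L     # one puddle, max at centre
  st <- frame_stack(fr, bit_depth = 8)
  de <- estimate_dose_per_pixel(st, n_patches = 8, patch_size = 11, seed = 1)
  expect_equal(de$dose_per_pixel, 1)
  set.seed(99)
  zero <- frame_stack(array(100L, c(11, 11, 40)) +
                        array(sample(0:2, 11 * 11 * 40, TRUE), c(11, 11, 40)),
                      bit_depth = 8)
  expect_equal(estimate_dose_per_pixel(zero, n_patches = 4, patch_size = 11,
                                       seed = 1)$dose_per_pixel, 0)
  expect_error(estimate_dose_per_pixel(st, patch_size = 4), "odd")
  expect_error(estimate_dose_per_pixel(st, patch_size = 13), "larger than frame")
})

test_that("simulated dose is recovered within 3 SE by patch counting", {
  cfg <- simulation_config(0.005, dims = c(48, 48), n_frames = 200,
                           shapes = shape_library("fixed_1px"),
                           amplitude_mean = 60, amplitude_sdlog = 0,
                           seed = 11)
  sim <- simulate_frames(cfg)
  de <- estimate_dose_per_pixel(sim$stack, n_patches = 64, patch_size = 11,
                                seed = 2)
  se <- sd(de$n_c) / sqrt(length(de$n_c))
  expect_lt(abs(de$dose_per_pixel - 0.005 * 200), max(3 * se, 0.15))
})

test_that("fine calibration counts no more events than on-the-fly counting", {
  cfg <- simulation_config(0.01, dims = c(32, 32), n_frames = 40, seed = 12)
  sim <- simulate_frames(cfg)
  calib <- sim_calibration(cfg, sigma = 3)
  fast <- count_frames(sim$stack, calib)
  fine <- count_frames(sim$stack, sim_calibration(cfg, sigma = 4),
                       common_mode = FALSE, min_area = 2)
  expect_lte(sum(fine$events_per_frame), sum(fast$events_per_frame))
})
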