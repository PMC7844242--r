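test_that("thresholding is strictly greater-than and respects dead pixels", {
  thr <- matrix(100, 4, 4)
  frame <- matrix(100L, 4, 4)
  calib <- calibration_frame(thr)
  expect_false(any(threshold_frame(frame, calib)))    # exactly at threshold
  frame[2, 3] <- 101L
  expect_equal(which(threshold_frame(frame, calib)), 2L + 2L * 4L)
  thr2 <- thr; thr2[2, 3] <- Inf
  expect_false(any(threshold_frame(frame, calibration_frame(thr2))))
  expect_error(threshold_frame(matrix(0L, 3, 3), calib), "shapes")
  set.seed(13)
  fr <- matrix(sample(0:200, 64, TRUE), 8, 8)
  th <- matrix(runif(64, 50, 150), 8, 8)
  expect_identical(threshold_frame(fr, calibration_frame(th)), fr > th)
})

test_that("puddle summary statistics match direct recomputation", {
  expect_equal(summarize_puddle(c(10, 30), "sum"), 40)
  expect_equal(summarize_puddle(c(10, 30), "max"), 30)
  expect_equal(summarize_puddle(c(10, 30), "mean"), 20)
  expect_equal(summarize_puddle(7, "sum"), 7)
  expect_equal(summarize_puddle(7, "max"), 7)
  expect_equal(summarize_puddle(7, "mean"), 7)
  set.seed(14)
  m <- rand_mask(16, 16, 0.25)
  fr <- matrix(sample(1:4000, 256, TRUE), 16, 16)
  ps <- label_components(m, fr)
  if (ps$n > 0) {
    expect_equal(summarize_puddle(ps, "sum"),
                 vapply(ps$values, sum, 0), ignore_attr = TRUE)
    expect_equal(summarize_puddle(ps, "max"),
                 vapply(ps$values, max, 0), ignore_attr = TRUE)
  }
})

test_that("localization strategies and the half-down tie-break", {
  px <- rbind(c(1, 1), c(1, 2))
  expect_equal(localize_puddle(px, c(10, 30), "max_pixel"), c(1L, 2L))
  sq <- as.matrix(expand.grid(1:2, 1:2))[, 2:1]       # uniform 2 x 2
  expect_equal(localize_puddle(sq, strategy = "unweighted_centroid"),
               c(1L, 1L))                             # centroid 1.5 -> top-left
  wc <- rbind(c(1, 1), c(1, 4))
  expect_equal(localize_puddle(wc, c(1, 3), "weighted_centroid"),
               c(1L, 3L))                             # col 3.25 -> 3
  expect_error(localize_puddle(wc, strategy = "max_pixel"), "requires ADU")
})

test_that("L3 payload is exactly ceiling(H*W/8) bytes with no intensities", {
  tf <- toy_frame(10, 10)
  rf <- reduce_frame(tf$frame, tf$calib, 3)
  expect_length(rf$binary_payload, 13)
  expect_null(rf$intensity_payload)
  expect_identical(expand_frame(rf), threshold_frame(tf$frame, tf$calib))
})

test_that("L4 reduces each puddle to one pixel", {
  fr <- matrix(0L, 8, 8)
  fr[3:4, 3:4] <- 200L
  calib <- calibration_frame(matrix(100, 8, 8))
  rf <- reduce_frame(fr, calib, 4)
  counted <- expand_frame(rf)
  expect_equal(sum(counted), 1L)
  expect_equal(counted[3, 3], 1L)          # half-down centroid of the square
  expect_equal(rf$n_puddles, 1L)
})

test_that("L1 reduction is lossless for supra-threshold pixels", {
  set.seed(15)
  for (i in 1:50) {
    h <- sample(6:24, 1); w <- sample(6:24, 1)
    fr <- matrix(sample(0L:4095L, h * w, TRUE) *
                   (runif(h * w) < 0.2), h, w)
    calib <- calibration_frame(matrix(150, h, w))
    rf <- reduce_frame(fr, calib, 1, bit_depth = 12)
    expect_identical(expand_frame(rf), ifelse(fr > 150L, fr, 0L))
  }
})

test_that("L2 statistics come back in label order", {
  fr <- matrix(0L, 6, 10)
  fr[1, 9] <- 500L                          # first-touch order: row-major
  fr[3, 2] <- 700L; fr[3, 3] <- 100L
  calib <- calibration_frame(matrix(50, 6, 10))
  rf <- reduce_frame(fr, calib, 2, statistic = "sum", bit_depth = 12)
  ex <- expand_frame(rf)
  expect_equal(ex$statistics, c(500L, 800L))
  expect_equal(rf$n_puddles, 2L)
  rfm <- reduce_frame(fr, calib, 2, statistic = "max", bit_depth = 12)
  expect_equal(expand_frame(rfm)$statistics, c(500L, 700L))
})

test_that("corrupted payloads raise errors, never silent wrong frames", {
  tf <- toy_frame()
  rf <- reduce_frame(tf$frame, tf$calib, 1, bit_depth = 12)
  bad <- rf
  bad$intensity_payload <- bad$intensity_payload[-1]
  expect_error(expand_frame(bad), "corrupted")
  bad2 <- rf
  bad2$binary_payload <- bad2$binary_payload[-1]
  expect_error(expand_frame(bad2), "corrupted")
  bad3 <- rf
  bad3$n_signal <- bad3$n_signal + 1L
  expect_error(expand_frame(bad3), "corrupted")
  rf2 <- reduce_frame(tf$frame, tf$calib, 2, bit_depth = 12)
  bad4 <- rf2
  bad4$intensity_payload <- c(bad4$intensity_payload, as.raw(0))
  expect_error(expand_frame(bad4), "corrupted")
})

test_that("invalid reduction level is rejected", {
  tf <- toy_frame()
  expect_error(reduce_frame(tf$frame, tf$calib, 5), "invalid reduction level")
})

test_that("centroid encodings agree across all three modes", {
  one <- matrix(c(1L, 1L), 1, 2)
  li <- encode_centroids(one, c(16, 16), "linear_index", bit_depth = 8)
  expect_identical(li, as.raw(c(0, 0)))              # one 16-bit word, value 0
  for (mode in c("binary_image", "linear_index", "rle"))
    expect_length(encode_centroids(matrix(integer(0), 0, 2), c(16, 16), mode), 0)
  set.seed(16)
  cent <- unique(cbind(sample.int(200, 1000, TRUE), sample.int(180, 1000, TRUE)))
  decoded <- lapply(c("binary_image", "linear_index", "rle"), function(mode) {
    pay <- encode_centroids(cent, c(200, 180), mode, bit_depth = 9)
    decode_centroids(pay, c(200, 180), mode, bit_depth = 9)
  })
  expect_identical(decoded[[1]], decoded[[2]])
  expect_identical(decoded[[1]], decoded[[3]])
  ord <- order(cent[, 1], cent[, 2])
  expect_equal(decoded[[1]], cent[ord, ], ignore_attr = TRUE)
  expect_error(encode_centroids(matrix(c(0L, 5L), 1, 2), c(16, 16)), "bounds")
})

test_that("level relationships hold on one frame", {
  set.seed(17)
  cfg <- simulation_config(0.01, dims = c(32, 32), n_frames = 1, seed = 17)
  sim <- simulate_frames(cfg)
  calib <- sim_calibration(cfg, sigma = 4)
  fr <- get_frame(sim$stack, 1)
  r1 <- reduce_frame(fr, calib, 1)
  r2 <- reduce_frame(fr, calib, 2)
  r3 <- reduce_frame(fr, calib, 3)
  r4 <- reduce_frame(fr, calib, 4)
  # L1-L3 share the binary map; L4's true pixels equal the puddle count
  expect_identical(r1$binary_payload, r3$binary_payload)
  expect_identical(r2$binary_payload, r3$binary_payload)
  expect_equal(r4$n_signal, r2$n_puddles)
  expect_equal(sum(expand_frame(r4)), r2$n_puddles)
})
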