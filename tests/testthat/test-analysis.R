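test_that("fixed polyplet enumeration matches exhaustive brute force", {
  expect_equal(enumerate_fixed_polyplets(1)$count, 1L)
  shapes2 <- enumerate_fixed_polyplets(2)
  expect_equal(shapes2$count, 4L)      # horizontal, vertical, two diagonals
  keys <- vapply(shapes2$shapes, function(m)
    paste(m[, 1], m[, 2], sep = ",", collapse = ";"), character(1))
  expect_setequal(keys, c("0,0;0,1", "0,0;1,0", "0,0;1,1", "0,1;1,0"))
  for (s in 1:5)
    expect_equal(enumerate_fixed_polyplets(s)$count, brute_polyplets(s))
  expect_error(enumerate_fixed_polyplets(0), "1..8")
  expect_error(enumerate_fixed_polyplets(9), "1..8")
})

test_that("counting accumulates one event per puddle, any strategy", {
  fr <- matrix(0L, 16, 16)
  fr[4:5, 4:5] <- 200L
  st <- frame_stack(array(fr, c(16, 16, 1)), bit_depth = 8)
  calib <- calibration_frame(matrix(100, 16, 16))
  res <- count_frames(st, calib)
  expect_equal(sum(res$counted), 1)
  cfg <- simulation_config(0.01, dims = c(32, 32), n_frames = 15, seed = 37)
  sim <- simulate_frames(cfg)
  calib2 <- sim_calibration(cfg, sigma = 4)
  per <- lapply(c("unweighted_centroid", "weighted_centroid", "max_pixel"),
                function(s) count_frames(sim$stack, calib2, strategy = s))
  counts <- vapply(per, function(r) sum(r$counted), 0)
  expect_equal(counts[2], counts[1])           # counts identical across
  expect_equal(counts[3], counts[1])           # strategies, positions differ
  for (r in per)
    expect_equal(sum(r$counted), sum(r$events_per_frame))  # conservation
})

test_that("simulated coincidence loss grows with dose and stamp size", {
  libs <- list(shape_library("fixed_1px"), shape_library("fixed_2x2"),
               shape_library("fixed_3x3"))
  doses <- c(0.005, 0.02, 0.05)
  loss <- vapply(libs, function(lib) vapply(doses, function(d)
    coincidence_loss_simulated(d, lib, c(256, 256), 30, seed = 38)$loss, 0),
    numeric(3))
  for (j in 1:3) expect_true(all(diff(loss[, j]) > 0))   # dose monotone
  for (i in 1:3) expect_true(all(diff(loss[i, ]) > 0))   # stamp monotone
})

test_that("8-connectivity loses at least as many events as 4-connectivity", {
  lib <- shape_library("fixed_1px")
  for (d in c(0.01, 0.05)) {
    l8 <- coincidence_loss_simulated(d, lib, c(256, 256), 25, seed = 39,
                                     connectivity = 8)$loss
    l4 <- coincidence_loss_simulated(d, lib, c(256, 256), 25, seed = 39,
                                     connectivity = 4)$loss
    expect_gte(l8, l4)
  }
})

test_that("sparse and dense coincidence paths agree statistically", {
  lib <- shape_library("fixed_2x2")
  dn <- coincidence_loss_simulated(0.002, lib, c(128, 128), 400, seed = 40,
                                   method = "dense")
  sp <- coincidence_loss_simulated(0.002, lib, c(128, 128), 400, seed = 41,
                                   method = "sparse")
  se <- sqrt(dn$standard_error^2 + sp$standard_error^2)
  expect_lt(abs(dn$loss - sp$loss), 4 * se)
})

test_that("the analytic size-distribution model behaves sanely", {
  expect_equal(coincidence_loss_analytic(0, c(1))$loss, 0)
  # degenerate all-1-pixel distribution: 9-pixel box neighbourhood
  for (lam in c(0.001, 0.005)) {
    an <- coincidence_loss_analytic(lam, c(1))$loss
    expect_equal(an, 1 - exp(-9 * lam))
    sim <- coincidence_loss_simulated(lam, shape_library("fixed_1px"),
                                      c(256, 256), 60, seed = 42)$loss
    expect_lt(abs(an / sim), 2.5)                # within ~2x of simulation
    expect_gt(an / sim, 1)                       # bounding boxes overestimate
  }
  # loss is monotone in mean puddle size
  l_small <- coincidence_loss_analytic(0.01, c(0.9, 0.1))$loss
  l_big <- coincidence_loss_analytic(0.01, c(0.1, 0.1, 0.2, 0.3, 0.15, 0.15))$loss
  expect_gt(l_big, l_small)
})

test_that("puddle statistics recover sizes and motifs", {
  m <- matrix(FALSE, 20, 20)
  for (p in list(c(2, 2), c(2, 10), c(10, 2), c(14, 14)))
    m[p[1]:(p[1] + 1), p[2]:(p[2] + 1)] <- TRUE    # four separated 2x2 squares
  stats <- puddle_statistics(m)
  expect_equal(stats$n_puddles, 4)
  expect_equal(as.integer(names(stats$size_histogram)), 4L)
  expect_equal(names(stats$motifs[["4"]])[1], "0,0;0,1;1,0;1,1")
  expect_equal(unname(stats$motifs[["4"]][1]), 4L, ignore_attr = TRUE)
  expect_equal(puddle_statistics(matrix(FALSE, 5, 5))$n_puddles, 0)
})

test_that("puddle statistics accept L1-L3 frames and reject L4", {
  tf <- toy_frame(16, 16, thr = 2000)
  rf1 <- reduce_frame(tf$frame, tf$calib, 1, bit_depth = 12)
  rf3 <- reduce_frame(tf$frame, tf$calib, 3)
  rf4 <- reduce_frame(tf$frame, tf$calib, 4)
  s1 <- puddle_statistics(list(rf1))
  s3 <- puddle_statistics(list(rf3))
  expect_equal(s1$size_histogram, s3$size_histogram)
  expect_error(puddle_statistics(list(rf4)), "no shape information")
})

test_that("sampled shape frequencies match the library weights", {
  lib <- shape_library("parametric", max_size = 3)
  cfg <- simulation_config(5e-4, dims = c(128, 128), n_frames = 120,
                           shapes = lib, amplitude_sdlog = 0,
                           amplitude_mean = 80, dark_sd = 1, seed = 43)
  sim <- simulate_frames(cfg)
  calib <- sim_calibration(cfg, sigma = 5)
  masks <- lapply(seq_len(n_frames(sim$stack)), function(i)
    threshold_frame(get_frame(sim$stack, i), calib))
  stats <- puddle_statistics(masks)
  got <- as.vector(stats$size_histogram[c("1", "2", "3")]) / stats$n_puddles
  want <- vapply(1:3, function(s) sum(lib$prob[lib$size == s]), 0)
  n <- stats$n_puddles
  for (s in 1:3)
    expect_lt(abs(got[s] - want[s]), 4 * sqrt(want[s] * (1 - want[s]) / n) + 0.02)
})

test_that("reduction-only L3 factor equals the bit depth ratio exactly", {
  bench <- benchmark_reduction_compression(0.01, levels = 3,
                                           dims = c(64, 64), n_frames = 4,
                                           seed = 44)
  expect_equal(bench$reduction_ratio, 16)
})

test_that("false-positive floor inverts exactly on noiseless series", {
  d0 <- 0.01; g <- 1 / 200; f <- 1e-6
  counted <- d0 * g^(0:3) + f
  fit <- estimate_false_positive_rate(counted, dilution = 200)
  expect_equal(fit$floor, f, tolerance = 1e-10)
  expect_equal(fit$d0, d0, tolerance = 1e-10)
  fit0 <- estimate_false_positive_rate(d0 * g^(0:3), dilution = 200)
  expect_lt(fit0$floor, 1e-12)
  expect_error(estimate_false_positive_rate(c(1, 2), 10), "at least 3")
  expect_warning(estimate_false_positive_rate(c(1e-3, 5e-3, 1e-2), 10),
                 "non-monotone")
})

test_that("backscatter estimation reports a clean null", {
  set.seed(45)
  ev <- data.frame(frame = rep(1:600, each = 4),
                   row = sample.int(256, 2400, TRUE),
                   col = sample.int(256, 2400, TRUE))
  est <- estimate_backscatter_ratio(ev, dims = c(256, 256), n_frames = 600,
                                    candidates = seq(0, 0.2, 0.05), seed = 46)
  expect_false(est$detectable)
  expect_identical(est$ratio, Inf)
  expect_error(estimate_backscatter_ratio(ev[1:50, ], c(256, 256), 600),
               "too few events")
})

test_that("doubling the event rate does not fake a backscatter signal", {
  set.seed(47)
  ev <- data.frame(frame = rep(1:600, each = 8),
                   row = sample.int(256, 4800, TRUE),
                   col = sample.int(256, 4800, TRUE))
  est <- estimate_backscatter_ratio(ev, dims = c(256, 256), n_frames = 600,
                                    candidates = seq(0, 0.2, 0.05), seed = 48)
  expect_lt(est$spawn_fraction, 0.03)
})
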