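test_that("zero dose produces pure dark noise and an empty event list", {
  cfg <- simulation_config(0, dims = c(24, 24), n_frames = 5, seed = 30)
  sim <- simulate_frames(cfg)
  expect_equal(nrow(sim$events), 0)
  expect_lt(max(abs(as.double(sim$stack$frames) - 100)), 6 * 4 + 1)
})

test_that("the same seed reproduces the full output", {
  cfg <- simulation_config(0.01, dims = c(32, 32), n_frames = 6, seed = 31,
                           backscatter = list(fraction = 0.1))
  a <- simulate_frames(cfg)
  b <- simulate_frames(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$events, b$events)
})

test_that("event counts follow the Poisson law", {
  cfg <- simulation_config(0.01, dims = c(256, 256), n_frames = 100,
                           shapes = shape_library("fixed_1px"), seed = 32)
  sim <- simulate_frames(cfg)
  expected <- 0.01 * 256^2 * 100
  expect_lt(abs(nrow(sim$events) - expected), 4 * sqrt(expected))
  per_frame <- tabulate(sim$events$frame, 100)
  expect_lt(abs(var(per_frame) / mean(per_frame) - 1), 0.5)  # index of dispersion
})

test_that("periodic stamping conserves intensity; clipping loses only edges", {
  lib <- shape_library("fixed_3x3")
  st <- recode:::stamp_events
  amp <- c(10, 20)
  # one interior event, one at the very corner
  per <- st(c(5L, 1L), c(5L, 1L), c(1L, 1L), lib, c(8L, 8L), "periodic",
            amplitudes = amp)
  expect_equal(sum(per), sum(amp * 9))
  clp <- st(c(5L, 1L), c(5L, 1L), c(1L, 1L), lib, c(8L, 8L), "clip",
            amplitudes = amp)
  expect_equal(sum(clp), 10 * 9 + 20 * 9)          # 3x3 anchored inside survives
  clp2 <- st(8L, 8L, 1L, lib, c(8L, 8L), "clip", amplitudes = 10)
  expect_equal(sum(clp2), 10)                      # corner anchor keeps 1 pixel
})

test_that("stamped signal pixels match the ground-truth events", {
  cfg <- simulation_config(0.003, dims = c(48, 48), n_frames = 20,
                           shapes = shape_library("fixed_2x2"),
                           amplitude_sdlog = 0, dark_sd = 0, seed = 33)
  sim <- simulate_frames(cfg)
  for (i in unique(sim$events$frame)) {
    ev <- sim$events[sim$events$frame == i, ]
    mask <- recode:::stamp_events(ev$row, ev$col, ev$shape, cfg$shapes,
                                  cfg$dims, "periodic")
    got <- get_frame(sim$stack, i) > cfg$dark_mean + 1
    expect_identical(got, mask)
  }
})

test_that("backscatter spawning follows the binomial law and merges at zero displacement", {
  ev <- data.frame(frame = rep(1:100, each = 1000),
                   row = sample.int(512, 1e5, TRUE),
                   col = sample.int(512, 1e5, TRUE),
                   shape = 1L, type = "primary")
  aug <- inject_backscatter(ev, fraction = 0, dims = c(512, 512))
  expect_identical(aug, ev)
  aug2 <- inject_backscatter(ev, fraction = 1 / 8.6, displacement_sd = 5,
                             dims = c(512, 512), seed = 34)
  spawned <- sum(aug2$type == "backscatter")
  p <- 1 / 8.6
  expect_lt(abs(spawned - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)))
  # zero displacement: the backscatter lands on its parent and merges
  small <- data.frame(frame = 1L, row = 10L, col = 10L, shape = 1L,
                      type = "primary")
  aug3 <- inject_backscatter(small, fraction = 0.999, displacement_sd = 0,
                             dims = c(32, 32), seed = 35)
  expect_equal(nrow(aug3), 2)
  expect_equal(aug3$row, c(10L, 10L))
  mask <- recode:::stamp_events(aug3$row, aug3$col, aug3$shape,
                                shape_library("fixed_1px"), c(32L, 32L),
                                "periodic")
  expect_equal(label_components(mask)$n, 1)
})

test_that("the parametric library favours small puddles as configured", {
  lib <- shape_library("parametric", max_size = 5)
  expect_equal(sum(lib$prob), 1)
  expect_equal(vapply(lib$offsets, nrow, 0L), lib$size)
  # ~80% of sampled puddles span fewer than three pixels
  expect_equal(sum(lib$prob[lib$size <= 2]), 0.8, tolerance = 0.02)
  # every shape contains the anchor offset (0, 0) first
  for (o in lib$offsets) expect_equal(unname(o[1, ]), c(0L, 0L))
  counts <- table(lib$size)
  expect_equal(unname(counts[["4"]]), 110L)
})

test_that("a dose series decays geometrically onto the false-positive floor", {
  base <- simulation_config(0.02, dims = c(64, 64), n_frames = 40,
                            shapes = shape_library("fixed_1px"),
                            amplitude_sdlog = 0, seed = 36)
  series <- simulate_dose_series(base, n_steps = 4, dilution = 10, fp_rate = 0)
  true_dose <- vapply(series, `[[`, 0, "true_dose")
  expect_equal(true_dose, 0.02 / 10^(0:3))
  counted <- vapply(series, function(s)
    nrow(s$events) / (64^2 * 40), 0)
  expect_equal(counted, true_dose, tolerance = 0.25)
  # with a floor, counted dose flattens instead of vanishing
  series_fp <- simulate_dose_series(base, n_steps = 4, dilution = 10,
                                    fp_rate = 5e-4)
  counted_fp <- vapply(series_fp, function(s)
    nrow(s$events) / (64^2 * 40), 0)
  expect_gt(counted_fp[4], 2e-4)
  expect_lt(counted[4], 1e-4)
})
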