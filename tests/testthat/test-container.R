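reduced_fixture <- function(n = 10, h = 16, w = 16, level = 3, seed = 22,
                            bit_depth = 12L) {
  set.seed(seed)
  stack <- frame_stack(array(sample(0L:4095L, h * w * n, TRUE) *
                               rbinom(h * w * n, 1, 0.1), c(h, w, n)),
                       bit_depth = bit_depth)
  calib <- calibration_frame(matrix(400, h, w))
  list(stack = stack, calib = calib,
       frames = lapply(seq_len(n), function(i)
         reduce_frame(get_frame(stack, i), calib, level,
                      bit_depth = bit_depth)))
}

test_that("a container roundtrips reduced frames sequentially and randomly", {
  fx <- reduced_fixture(10)
  path <- withr::local_tempfile(fileext = ".rc3")
  con <- write_reduced(fx$frames, path, codec_spec("zstd"))
  expect_equal(nrow(con$index), 10)
  for (i in 1:10)
    expect_identical(expand_frame(read_frame(con, i)),
                     expand_frame(fx$frames[[i]]))
  # random access equals sequential access
  rnd <- lapply(c(7, 2, 5), function(i) expand_frame(read_frame(con, i)))
  seqd <- lapply(1:10, function(i) expand_frame(read_frame(con, i)))
  expect_identical(rnd, seqd[c(7, 2, 5)])
  info <- container_info(con)
  expect_equal(info$n_frames, 10)
  expect_equal(info$level, 3L)
  expect_true(info$finalized)
})

test_that("raw retention stores bit-identical source frames at intervals", {
  fx <- reduced_fixture(10, level = 1)
  path <- withr::local_tempfile()
  con <- write_reduced(fx$frames, path, raw_retention_interval = 5,
                       source_stack = fx$stack)
  expect_equal(sum(con$index$raw), 2)              # frames 5 and 10
  expect_equal(con$index$frame_number[con$index$raw], c(5, 10))
  expect_identical(read_raw_frame(con, 5), get_frame(fx$stack, 5))
  expect_identical(read_raw_frame(con, 10), get_frame(fx$stack, 10))
  expect_error(read_raw_frame(con, 3), "not retained")
})

test_that("interleaved part files merge into strictly frame-ordered output", {
  fx <- reduced_fixture(6)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "p1"); p2 <- file.path(d, "p2"); out <- file.path(d, "m")
  write_reduced(fx$frames[c(1, 3, 5)], p1, frame_numbers = c(1, 3, 5),
                finalize = FALSE)
  write_reduced(fx$frames[c(2, 4, 6)], p2, frame_numbers = c(2, 4, 6),
                finalize = FALSE)
  mg <- merge_parts(c(p1, p2), out)
  expect_equal(mg$index$frame_number, 1:6)
  for (i in 1:6)
    expect_identical(expand_frame(read_frame(mg, i)),
                     expand_frame(fx$frames[[i]]))
  # verbatim copy: compressed payload bytes unchanged by the merge
  part <- read_container(p1)
  expect_equal(mg$index$len_binary[mg$index$frame_number %in% c(1, 3, 5)],
               part$index$len_binary)
})

test_that("a single part merges into an equivalent finalized container", {
  fx <- reduced_fixture(4)
  d <- withr::local_tempdir()
  write_reduced(fx$frames, file.path(d, "p"), finalize = FALSE)
  mg <- merge_parts(file.path(d, "p"), file.path(d, "m"))
  expect_true(mg$header$finalized)
  for (i in 1:4)
    expect_identical(expand_frame(read_frame(mg, i)),
                     expand_frame(fx$frames[[i]]))
})

test_that("duplicate or missing frame numbers are rejected with specifics", {
  fx <- reduced_fixture(4)
  d <- withr::local_tempdir()
  write_reduced(fx$frames[1:2], file.path(d, "a"), frame_numbers = c(1, 2),
                finalize = FALSE)
  write_reduced(fx$frames[3:4], file.path(d, "b"), frame_numbers = c(2, 4),
                finalize = FALSE)
  expect_error(merge_parts(file.path(d, c("a", "b")), file.path(d, "m")),
               "duplicate.*2")
  write_reduced(fx$frames[3:4], file.path(d, "c"), frame_numbers = c(4, 5),
                finalize = FALSE)
  expect_error(merge_parts(file.path(d, c("a", "c")), file.path(d, "m")),
               "missing frame numbers: 3")
})

test_that("mixed headers across parts are rejected", {
  fx <- reduced_fixture(2)
  fx4 <- reduced_fixture(2, level = 4, seed = 23)
  d <- withr::local_tempdir()
  write_reduced(fx$frames, file.path(d, "a"), frame_numbers = 1:2,
                finalize = FALSE)
  write_reduced(fx4$frames, file.path(d, "b"), frame_numbers = 3:4,
                finalize = FALSE)
  expect_error(merge_parts(file.path(d, c("a", "b")), file.path(d, "m")),
               "header mismatch")
})

test_that("mixed levels in one write are rejected", {
  fx <- reduced_fixture(2)
  fx4 <- reduced_fixture(2, level = 4, seed = 23)
  expect_error(write_reduced(c(fx$frames[1], fx4$frames[1]), tempfile()),
               "mixed reduction levels")
})

test_that("payload damage is confined to the damaged frame", {
  fx <- reduced_fixture(6, level = 1)
  path <- withr::local_tempfile()
  con <- write_reduced(fx$frames, path)
  # flip one byte inside frame 4's binary payload
  off <- con$index$offset[4] + recode:::.record_header_len + 15
  f <- file(path, "r+b")
  seek(f, off)
  b <- readBin(f, "raw", 1)
  seek(f, off, rw = "write")
  writeBin(as.raw(bitwXor(as.integer(b), 255L)), f)
  close(f)
  con2 <- read_container(path)
  expect_error(read_frame(con2, 4), "checksum")
  for (i in c(1:3, 5:6))
    expect_identical(expand_frame(read_frame(con2, i)),
                     expand_frame(fx$frames[[i]]))
})

test_that("truncated part files are detected", {
  fx <- reduced_fixture(3)
  path <- withr::local_tempfile()
  write_reduced(fx$frames, path, finalize = FALSE)
  sz <- file.size(path)
  truncated <- withr::local_tempfile()
  file.copy(path, truncated)
  con <- file(truncated, "r+b"); truncate_at <- sz - 5
  seek(con, 0); raw_all <- readBin(con, "raw", truncate_at); close(con)
  writeBin(raw_all, truncated)
  expect_error(read_container(truncated), "corruption")
})

test_that("out-of-range frame numbers are rejected", {
  fx <- reduced_fixture(3)
  con <- write_reduced(fx$frames, withr::local_tempfile())
  expect_error(read_frame(con, 99), "out of range")
  expect_error(read_frame(con, 0), "out of range")
})
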