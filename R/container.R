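# On-disk container layout (little-endian, all integers unsigned):
#
#   header (512 bytes):
#     "RCDE" | version u32 | level u8 | codec u8 | opt u8 | prefilter u8
#     chunk_size u32 | height u32 | width u32 | bit_depth u32
#     statistic u8 | strategy u8 | connectivity u8 | finalized u8
#     n_frames u64 | frame_rate f64 | calib_crc u32 | meta char[64]
#     zero padding to 512
#   per-frame records, appended in frame order:
#     frame_number u64 | timestamp u64
#     len_binary u32 | len_intensity u32 | len_raw u32 | flags u32 (bit0 raw)
#     n_signal u32 | n_puddles u32 (0xFFFFFFFF = not recorded)
#     crc_binary u32 | crc_intensity u32 | crc_raw u32
#     binary block | intensity block | raw frame bytes
#   footer (finalized files only; part files stop after the last record):
#     n u64 | n x (frame_number u64, offset u64) | index_offset u64 | "RCIX"
#
# Payload blocks are the self-describing compressed blocks of
# compress_block(); raw frames are uncompressed row-major pixels at
# ceiling(bit_depth / 8) bytes per pixel. CRC-32 per payload catches
# truncation and bit rot at the damaged frame only.

.container_magic <- charToRaw("RCDE")
.footer_magic <- charToRaw("RCIX")
.header_len <- 512L
.record_header_len <- 52L
.stat_ids <- c(max = 1L, sum = 2L, mean = 3L)
.strategy_ids <- c(unweighted_centroid = 1L, weighted_centroid = 2L,
                   max_pixel = 3L)

container_header_raw <- function(h) {
  meta <- charToRaw(substr(h$meta %||% "", 1, 64))
  out <- c(.container_magic,
           u32_to_raw(1L),
           as.raw(c(h$level, .codec_ids[[h$codec$algorithm]],
                    .opt_ids[[h$codec$optimization]],
                    .prefilter_ids[[h$codec$prefilter]])),
           u32_to_raw(h$codec$chunk_size),
           u32_to_raw(h$dims[1]), u32_to_raw(h$dims[2]),
           u32_to_raw(h$bit_depth),
           as.raw(c(.stat_ids[[h$statistic]], .strategy_ids[[h$strategy]],
                    h$connectivity, as.integer(h$finalized))),
           u64_to_raw(h$n_frames),
           writeBin(as.double(h$frame_rate %||% NaN), raw(), size = 8,
                    endian = "little"),
           u32_to_raw(h$calib_crc %||% 0),
           meta, raw(64L - length(meta)))
  c(out, raw(.header_len - length(out)))
}

parse_container_header <- function(r) {
  if (!identical(r[1:4], .container_magic))
    stop("format error: not a recode container (bad magic)")
  codec <- codec_spec(names(.codec_ids)[match(as.integer(r[10]), .codec_ids)],
                      names(.opt_ids)[match(as.integer(r[11]), .opt_ids)],
                      names(.prefilter_ids)[match(as.integer(r[12]), .prefilter_ids)],
                      raw_to_u32(r[13:16]))
  fr <- readBin(r[41:48], "double", 1, size = 8, endian = "little")
  list(version = raw_to_u32(r[5:8]),
       level = as.integer(r[9]),
       codec = codec,
       dims = c(raw_to_u32(r[17:20]), raw_to_u32(r[21:24])),
       bit_depth = raw_to_u32(r[25:28]),
       statistic = names(.stat_ids)[match(as.integer(r[29]), .stat_ids)],
       strategy = names(.strategy_ids)[match(as.integer(r[30]), .strategy_ids)],
       connectivity = as.integer(r[31]),
       finalized = as.integer(r[32]) == 1L,
       n_frames = raw_to_u64(r[33:40]),
       frame_rate = if (is.nan(fr)) NULL else fr,
       calib_crc = raw_to_u32(r[49:52]),
       meta = rawToChar(r[53:116][r[53:116] != as.raw(0)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_raw <- function(rf, codec, frame_number, timestamp, raw_frame = NULL,
                       bit_depth) {
  blk_b <- compress_block(rf$binary_payload, codec)
  blk_i <- if (is.null(rf$intensity_payload)) raw(0)
           else compress_block(rf$intensity_payload, codec)
  blk_r <- if (is.null(raw_frame)) raw(0)
           else frame_to_bytes(raw_frame, bit_depth)
  c(u64_to_raw(frame_number), u64_to_raw(timestamp),
    u32_to_raw(length(blk_b)), u32_to_raw(length(blk_i)),
    u32_to_raw(length(blk_r)),
    u32_to_raw(if (is.null(raw_frame)) 0L else 1L),
    u32_to_raw(rf$n_signal),
    u32_to_raw(if (is.na(rf$n_puddles)) 4294967295 else rf$n_puddles),
    u32_to_raw(crc32_raw(blk_b)), u32_to_raw(crc32_raw(blk_i)),
    u32_to_raw(crc32_raw(blk_r)),
    blk_b, blk_i, blk_r)
}

frame_to_bytes <- function(frame, bit_depth) {
  v <- as.integer(t(frame))
  if (bit_depth <= 8L) as.raw(v)
  else writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2,
                endian = "little")
}

bytes_to_frame <- function(bytes, dims, bit_depth) {
  v <- if (bit_depth <= 8L) as.integer(bytes)
       else {
         x <- readBin(bytes, "integer", length(bytes) / 2, size = 2,
                      signed = TRUE, endian = "little")
         ifelse(x < 0L, x + 65536L, x)
       }
  matrix(v, dims[1], dims[2], byrow = TRUE)
}

#' Write reduced frames to a container or part file
#'
#' Appends the reduced frames in order; with `finalize = TRUE` an index
#' footer is written for O(1) random access (a "part" file written by one
#' worker omits the footer and is indexed by scanning). Optionally retains
#' raw (unreduced, uncompressed) source frames at fixed intervals for
#' validation and post-hoc recalibration.
#'
#' @param frames list of `reduced_frame`s sharing level/shape/bit depth.
#' @param path output file.
#' @param codec a [codec_spec()].
#' @param frame_numbers integer frame numbers (default `1:n`).
#' @param timestamps monotonic integer timestamps (default
#'   `frame_numbers - 1`).
#' @param raw_retention_interval keep every k-th frame's raw pixels
#'   (requires `source_stack`); `NULL` disables retention.
#' @param source_stack the [frame_stack()] the frames came from (only
#'   needed for raw retention).
#' @param frame_rate,calib_crc,meta header metadata.
#' @param finalize write the index footer (`FALSE` for part files).
#' @return a `recode_container` handle (invisibly), as from
#'   [read_container()].
#' @export
write_reduced <- function(frames, path, codec = default_codec(),
                          frame_numbers = NULL, timestamps = NULL,
                          raw_retention_interval = NULL, source_stack = NULL,
                          frame_rate = NULL, calib_crc = 0, meta = "",
                          finalize = TRUE) {
  if (length(frames) == 0L) stop("no frames to write")
  lvl <- unique(vapply(frames, `[[`, integer(1), "level"))
  if (length(lvl) != 1L) stop("mixed reduction levels in one container")
  dims <- frames[[1]]$dims
  bd <- frames[[1]]$bit_depth
  for (f in frames)
    if (!identical(f$dims, dims) || f$bit_depth != bd)
      stop("frames do not share shape/bit_depth")
  frame_numbers <- frame_numbers %||% seq_along(frames)
  timestamps <- timestamps %||% (frame_numbers - 1)
  hdr <- list(level = lvl, codec = codec, dims = dims, bit_depth = bd,
              statistic = frames[[1]]$statistic, strategy = frames[[1]]$strategy,
              connectivity = frames[[1]]$connectivity, finalized = finalize,
              n_frames = length(frames), frame_rate = frame_rate,
              calib_crc = calib_crc, meta = meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(container_header_raw(hdr), con)
  offsets <- numeric(length(frames))
  pos <- .header_len
  for (i in seq_along(frames)) {
    raw_frame <- NULL
    if (!is.null(raw_retention_interval) &&
        frame_numbers[i] %% raw_retention_interval == 0L) {
      if (is.null(source_stack))
        stop("raw retention requires `source_stack`")
      raw_frame <- get_frame(source_stack, frame_numbers[i])
    }
    rec <- record_raw(frames[[i]], codec, frame_numbers[i], timestamps[i],
                      raw_frame, bd)
    offsets[i] <- pos
    writeBin(rec, con)
    pos <- pos + length(rec)
  }
  if (finalize)
    writeBin(footer_raw(frame_numbers, offsets, pos), con)
  close(con)
  on.exit(NULL)
  invisible(read_container(path))
}

footer_raw <- function(frame_numbers, offsets, index_offset) {
  entries <- lapply(seq_along(frame_numbers), function(i)
    c(u64_to_raw(frame_numbers[i]), u64_to_raw(offsets[i])))
  c(u64_to_raw(length(frame_numbers)), do.call(c, entries),
    u64_to_raw(index_offset), .footer_magic)
}

#' Open a container or part file
#'
#' Finalized containers are indexed from the footer; part files are
#' indexed by scanning the records sequentially.
#'
#' @param path container file.
#' @return a `recode_container`: list with `path`, `header` and an `index`
#'   data frame (`frame_number`, `offset`, `timestamp`, payload lengths,
#'   `raw` flag, `n_signal`, `n_puddles`).
#' @export
read_container <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < .header_len) stop("not a recode container: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- parse_container_header(readBin(con, "raw", .header_len))
  index <- if (header$finalized) read_footer_index(con, sz)
           else scan_index(con, sz)
  # per-record metadata comes from the record headers in both cases
  meta <- lapply(index$offset, function(off) {
    seek(con, off)
    parse_record_header(readBin(con, "raw", .record_header_len))
  })
  index$timestamp <- vapply(meta, `[[`, numeric(1), "timestamp")
  index$len_binary <- vapply(meta, `[[`, numeric(1), "len_binary")
  index$len_intensity <- vapply(meta, `[[`, numeric(1), "len_intensity")
  index$len_raw <- vapply(meta, `[[`, numeric(1), "len_raw")
  index$raw <- vapply(meta, `[[`, logical(1), "raw")
  index$n_signal <- vapply(meta, `[[`, numeric(1), "n_signal")
  index$n_puddles <- vapply(meta, `[[`, numeric(1), "n_puddles")
  fn <- vapply(meta, `[[`, numeric(1), "frame_number")
  if (!identical(fn, index$frame_number))
    stop("corruption error: index and record frame numbers disagree")
  structure(list(path = path, header = header, index = index),
            class = "recode_container")
}

read_footer_index <- function(con, sz) {
  seek(con, sz - 12)
  tail <- readBin(con, "raw", 12)
  if (!identical(tail[9:12], .footer_magic))
    stop("corruption error: missing index footer")
  index_offset <- raw_to_u64(tail[1:8])
  seek(con, index_offset)
  n <- raw_to_u64(readBin(con, "raw", 8))
  entries <- readBin(con, "raw", n * 16)
  if (length(entries) < n * 16) stop("corruption error: truncated index")
  m <- matrix(entries, nrow = 16)
  data.frame(
    frame_number = apply(m[1:8, , drop = FALSE], 2, raw_to_u64),
    offset = apply(m[9:16, , drop = FALSE], 2, raw_to_u64))
}

parse_record_header <- function(r) {
  if (length(r) < .record_header_len)
    stop("corruption error: truncated record header")
  list(frame_number = raw_to_u64(r[1:8]),
       timestamp = raw_to_u64(r[9:16]),
       len_binary = raw_to_u32(r[17:20]),
       len_intensity = raw_to_u32(r[21:24]),
       len_raw = raw_to_u32(r[25:28]),
       raw = bitwAnd(raw_to_u32(r[29:32]), 1) == 1,
       n_signal = raw_to_u32(r[33:36]),
       n_puddles = raw_to_u32(r[37:40]),
       crc_binary = raw_to_u32(r[41:44]),
       crc_intensity = raw_to_u32(r[45:48]),
       crc_raw = raw_to_u32(r[49:52]))
}

scan_index <- function(con, sz) {
  seek(con, .header_len)
  offsets <- numeric(0)
  fns <- numeric(0)
  pos <- .header_len
  while (pos + .record_header_len <= sz) {
    seek(con, pos)
    rh <- parse_record_header(readBin(con, "raw", .record_header_len))
    offsets <- c(offsets, pos)
    fns <- c(fns, rh$frame_number)
    pos <- pos + .record_header_len + rh$len_binary + rh$len_intensity + rh$len_raw
  }
  if (pos != sz)
    stop("corruption error: trailing bytes after last record")
  data.frame(frame_number = fns, offset = offsets)
}

#' @export
print.recode_container <- function(x, ...) {
  h <- x$header
  cat(sprintf("<recode_container> %s\n  L%d, %d x %d, %d-bit, %d frame(s), codec %s (%s)%s\n",
              x$path, h$level, h$dims[1], h$dims[2], h$bit_depth,
              nrow(x$index), h$codec$algorithm, h$codec$optimization,
              if (h$finalized) "" else " [part file]"))
  invisible(x)
}

#' Random access to one reduced frame
#'
#' Reads, CRC-checks and decompresses a single frame's record without
#' touching any other frame's payload; random access is bit-identical to a
#' sequential scan.
#'
#' @param container a `recode_container` from [read_container()].
#' @param i frame number (as stored).
#' @return a `reduced_frame`.
#' @export
read_frame <- function(container, i) {
  row <- match(i, container$index$frame_number)
  if (is.na(row))
    stop(sprintf("frame %s out of range", format(i)))
  con <- file(container$path, "rb")
  on.exit(close(con))
  seek(con, container$index$offset[row])
  rh <- parse_record_header(readBin(con, "raw", .record_header_len))
  blk_b <- readBin(con, "raw", rh$len_binary)
  blk_i <- readBin(con, "raw", rh$len_intensity)
  if (length(blk_b) < rh$len_binary || length(blk_i) < rh$len_intensity)
    stop("corruption error: truncated payload at frame ", format(i))
  if (crc32_raw(blk_b) != rh$crc_binary ||
      crc32_raw(blk_i) != rh$crc_intensity)
    stop("corruption error: payload checksum mismatch at frame ", format(i))
  h <- container$header
  structure(list(level = h$level, dims = h$dims, bit_depth = h$bit_depth,
                 binary_payload = decompress_block(blk_b),
                 intensity_payload = if (rh$len_intensity > 0)
                   decompress_block(blk_i),
                 n_signal = as.integer(rh$n_signal),
                 n_puddles = if (rh$n_puddles == 4294967295) NA_integer_
                             else as.integer(rh$n_puddles),
                 statistic = h$statistic, strategy = h$strategy,
                 connectivity = h$connectivity),
            class = "reduced_frame")
}

#' Read a retained raw frame
#'
#' @param container a `recode_container`.
#' @param i frame number; must carry the raw-retention flag.
#' @return integer `H x W` matrix of original pixels.
#' @export
read_raw_frame <- function(container, i) {
  row <- match(i, container$index$frame_number)
  if (is.na(row)) stop(sprintf("frame %s out of range", format(i)))
  if (!container$index$raw[row])
    stop(sprintf("frame %s was not retained raw", format(i)))
  con <- file(container$path, "rb")
  on.exit(close(con))
  seek(con, container$index$offset[row])
  rh <- parse_record_header(readBin(con, "raw", .record_header_len))
  seek(con, container$index$offset[row] + .record_header_len +
         rh$len_binary + rh$len_intensity)
  bytes <- readBin(con, "raw", rh$len_raw)
  if (length(bytes) < rh$len_raw || crc32_raw(bytes) != rh$crc_raw)
    stop("corruption error: raw payload damaged at frame ", format(i))
  bytes_to_frame(bytes, container$header$dims, container$header$bit_depth)
}

#' Merge part files into one time-ordered container
#'
#' Workers write disjoint subsets of frames to part files; merging
#' interleaves the records into strictly increasing frame order, copying
#' the compressed payload bytes verbatim (no re-compression), and writes a
#' finalized header plus index footer.
#'
#' @param part_paths character vector of part files (or containers).
#' @param path output merged container.
#' @return the merged `recode_container` (invisibly).
#' @export
merge_parts <- function(part_paths, path) {
  parts <- lapply(part_paths, read_container)
  h0 <- parts[[1]]$header
  for (p in parts[-1]) {
    h <- p$header
    same <- identical(h$level, h0$level) && identical(h$dims, h0$dims) &&
      identical(h$bit_depth, h0$bit_depth) &&
      identical(unclass(h$codec), unclass(h0$codec)) &&
      identical(h$statistic, h0$statistic) &&
      identical(h$strategy, h0$strategy) &&
      identical(h$connectivity, h0$connectivity)
    if (!same) stop("header mismatch between part files")
  }
  all_fn <- unlist(lapply(parts, function(p) p$index$frame_number))
  if (anyDuplicated(all_fn))
    stop("duplicate frame numbers across parts: ",
         paste(unique(all_fn[duplicated(all_fn)]), collapse = ", "))
  want <- seq(min(all_fn), max(all_fn))
  missing <- setdiff(want, all_fn)
  if (length(missing))
    stop("missing frame numbers: ", paste(missing, collapse = ", "))
  src <- data.frame(
    part = rep(seq_along(parts), vapply(parts, function(p) nrow(p$index), 0)),
    frame_number = all_fn,
    offset = unlist(lapply(parts, function(p) p$index$offset)),
    bytes = unlist(lapply(parts, function(p)
      .record_header_len + p$index$len_binary + p$index$len_intensity +
        p$index$len_raw)))
  src <- src[order(src$frame_number), ]
  h0$n_frames <- nrow(src)
  h0$finalized <- TRUE
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(container_header_raw(h0), con)
  pos <- .header_len
  offsets <- numeric(nrow(src))
  handles <- lapply(part_paths, function(p) file(p, "rb"))
  on.exit({for (h in handles) close(h); close(con)})
  for (i in seq_len(nrow(src))) {
    hin <- handles[[src$part[i]]]
    seek(hin, src$offset[i])
    rec <- readBin(hin, "raw", src$bytes[i])
    offsets[i] <- pos
    writeBin(rec, con)
    pos <- pos + length(rec)
  }
  writeBin(footer_raw(src$frame_number, offsets, pos), con)
  for (h in handles) close(h)
  close(con)
  on.exit(NULL)
  invisible(read_container(path))
}

#' Summarize a container
#'
#' @param container a `recode_container` (or path).
#' @return list with header fields and per-frame payload statistics.
#' @export
container_info <- function(container) {
  if (is.character(container)) container <- read_container(container)
  h <- container$header
  idx <- container$index
  list(level = h$level, dims = h$dims, bit_depth = h$bit_depth,
       codec = h$codec, n_frames = nrow(idx),
       n_raw_frames = sum(idx$raw),
       total_signal_pixels = sum(idx$n_signal),
       compressed_payload_bytes = sum(idx$len_binary + idx$len_intensity),
       file_bytes = file.size(container$path),
       finalized = h$finalized)
}
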