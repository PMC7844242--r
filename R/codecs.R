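# codec id registry (stable on-disk byte values)
.codec_ids <- c(deflate = 1L, zstd = 2L, bzip2 = 3L, lzma = 4L,
                lz4 = 5L, snappy = 6L)
.opt_ids <- c(optimal_speed = 0L, optimal_compression = 1L)
.prefilter_ids <- c(none = 0L, bitshuffle = 1L)

#' Lossless codec specification
#'
#' Selects one of the six supported lossless compression algorithms, one of
#' the two extreme internal optimization presets of that algorithm, and an
#' optional bitshuffle prefilter applied in chunks before compression.
#' Binary-map and intensity payloads are always compressed independently
#' with the chosen spec.
#'
#' @param algorithm `"deflate"`, `"zstd"`, `"bzip2"`, `"lzma"`, `"lz4"` or
#'   `"snappy"` (snappy has a single preset; both optimization levels map
#'   to it).
#' @param optimization `"optimal_speed"` (the library's fastest preset) or
#'   `"optimal_compression"` (its strongest).
#' @param prefilter `"none"` or `"bitshuffle"`.
#' @param chunk_size prefilter chunk size in bytes (default 2^16).
#' @return an object of class `codec_spec`.
#' @export
codec_spec <- function(algorithm = c("deflate", "zstd", "bzip2", "lzma",
                                     "lz4", "snappy"),
                       optimization = c("optimal_speed", "optimal_compression"),
                       prefilter = c("none", "bitshuffle"),
                       chunk_size = 65536L) {
  algorithm <- match.arg(algorithm)
  optimization <- match.arg(optimization)
  prefilter <- match.arg(prefilter)
  chunk_size <- as.integer(chunk_size)
  if (prefilter != "none" && chunk_size <= 0L)
    stop("`chunk_size` must be positive when the prefilter is active")
  structure(list(algorithm = algorithm, optimization = optimization,
                 prefilter = prefilter, chunk_size = chunk_size),
            class = "codec_spec")
}

#' @export
print.codec_spec <- function(x, ...) {
  cat(sprintf("<codec_spec> %s (%s)%s\n", x$algorithm, x$optimization,
              if (x$prefilter == "none") ""
              else sprintf(", bitshuffle prefilter (%d-byte chunks)", x$chunk_size)))
  invisible(x)
}

#' The reference codec
#'
#' Deflate at its fastest internal level ("Deflate-1"), no prefilter: the
#' reference algorithm for reduction-compression benchmarking, a good
#' average case between speed and compression power.
#'
#' @return a [codec_spec()].
#' @export
default_codec <- function() codec_spec("deflate", "optimal_speed", "none")

codec_compress_raw <- function(payload, algorithm, optimization) {
  fast <- optimization == "optimal_speed"
  switch(algorithm,
    deflate = .Call(C_deflate_compress, payload, if (fast) 1L else 9L),
    zstd = .Call(C_zstd_compress, payload,
                 if (fast) 1L else .Call(C_zstd_max_level)),
    bzip2 = .Call(C_bzip2_compress, payload, if (fast) 1L else 9L),
    lzma = .Call(C_lzma_compress, payload, if (fast) 0L else 9L),
    lz4 = .Call(C_lz4_compress, payload, !fast),
    snappy = .Call(C_snappy_compress, payload),
    stop("unknown codec: ", algorithm))
}

codec_decompress_raw <- function(stream, algorithm, orig_size) {
  switch(algorithm,
    deflate = .Call(C_deflate_decompress, stream, as.double(orig_size)),
    zstd = .Call(C_zstd_decompress, stream, as.double(orig_size)),
    bzip2 = .Call(C_bzip2_decompress, stream, as.double(orig_size)),
    lzma = .Call(C_lzma_decompress, stream, as.double(orig_size)),
    lz4 = .Call(C_lz4_decompress, stream, as.double(orig_size)),
    snappy = .Call(C_snappy_decompress, stream, as.double(orig_size)),
    stop("unknown codec: ", algorithm))
}

#' Bitshuffle a byte stream
#'
#' Gathers the i-th bit of every byte of each chunk into contiguous bit
#' planes (and back). Used as an optional prefilter before compression; it
#' never changes the decompressed content.
#'
#' @param data raw vector.
#' @param chunk_size chunk length in bytes.
#' @param inverse if `TRUE`, undo the shuffle.
#' @return raw vector of the same length.
#' @export
bitshuffle <- function(data, chunk_size = 65536L, inverse = FALSE) {
  if (length(data) == 0L) return(data)
  if (inverse) .Call(C_bitunshuffle, data, as.double(chunk_size))
  else .Call(C_bitshuffle, data, as.double(chunk_size))
}

# self-describing block header: [codec u8][opt u8][prefilter u8][reserved u8]
# [chunk_size u32 LE][orig_len u32 LE], then the compressed stream
.block_header_len <- 12L

#' Compress a payload into a self-describing block
#'
#' Applies the spec's prefilter and codec; the resulting block stores the
#' codec registry ids and original length in a 12-byte header, so
#' [decompress_block()] needs no side information. An empty payload
#' encodes as a header-only block.
#'
#' @param payload raw vector.
#' @param spec a [codec_spec()].
#' @return raw block.
#' @export
compress_block <- function(payload, spec = default_codec()) {
  if (!inherits(spec, "codec_spec")) stop("`spec` must be a codec_spec")
  hdr <- c(as.raw(.codec_ids[[spec$algorithm]]),
           as.raw(.opt_ids[[spec$optimization]]),
           as.raw(.prefilter_ids[[spec$prefilter]]),
           as.raw(0L),
           u32_to_raw(spec$chunk_size),
           u32_to_raw(length(payload)))
  if (length(payload) == 0L) return(hdr)
  if (spec$prefilter == "bitshuffle")
    payload <- bitshuffle(payload, spec$chunk_size)
  c(hdr, codec_compress_raw(payload, spec$algorithm, spec$optimization))
}

#' Decompress a self-describing block
#'
#' @param block raw block produced by [compress_block()].
#' @return the original raw payload. Unknown codec ids raise a format
#'   error; corrupted streams surface the codec's error.
#' @export
decompress_block <- function(block) {
  if (length(block) < .block_header_len)
    stop("format error: block shorter than its header")
  cid <- as.integer(block[1])
  algorithm <- names(.codec_ids)[match(cid, .codec_ids)]
  if (is.na(algorithm)) stop("format error: unknown codec id ", cid)
  opt <- names(.opt_ids)[match(as.integer(block[2]), .opt_ids)]
  pf <- names(.prefilter_ids)[match(as.integer(block[3]), .prefilter_ids)]
  if (is.na(opt) || is.na(pf)) stop("format error: unknown optimization/prefilter id")
  chunk_size <- raw_to_u32(block[5:8])
  orig_len <- raw_to_u32(block[9:12])
  if (orig_len == 0) return(raw(0))
  payload <- codec_decompress_raw(block[-seq_len(.block_header_len)],
                                  algorithm, orig_len)
  if (pf == "bitshuffle") payload <- bitshuffle(payload, chunk_size, inverse = TRUE)
  payload
}

#' All supported codec specifications
#'
#' @return list of [codec_spec()] covering the 6 algorithms x 2
#'   optimization levels x 2 prefilters.
#' @export
all_codec_specs <- function() {
  grid <- expand.grid(a = names(.codec_ids), o = names(.opt_ids),
                      p = names(.prefilter_ids), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    codec_spec(grid$a[i], grid$o[i], grid$p[i]))
}
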