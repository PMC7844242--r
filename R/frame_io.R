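#' Read a dense frame stack from disk
#'
#' Reads movie-mode detector data either from a headerless raw binary frame
#' sequence (little-endian, frame-sequential, as written by sequence-file
#' acquisition software; an optional fixed-size file header can be skipped)
#' or from an MRC/MRCS stack.
#'
#' @param path file to read.
#' @param layout `"raw"` or `"mrc"`.
#' @param dims for `layout = "raw"`: integer `c(height, width)` of one frame.
#' @param dtype for `layout = "raw"`: `"uint8"` or `"uint16"`.
#' @param bit_depth declared bits per pixel; defaults to the dtype width.
#' @param header_skip for `layout = "raw"`: bytes to skip before the first
#'   frame (accommodates vendor sequence-file headers).
#' @param frame_rate optional frames/second metadata.
#' @return a [frame_stack()]. Pixel values are returned untouched; frame `i`
#'   of the file becomes frame `i` of the stack.
#' @export
read_frame_stack <- function(path, layout = c("raw", "mrc"), dims = NULL,
                             dtype = c("uint16", "uint8"), bit_depth = NULL,
                             header_skip = 0L, frame_rate = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "mrc") return(read_mrc(path, frame_rate = frame_rate))
  dtype <- match.arg(dtype)
  if (is.null(dims) || length(dims) != 2L)
    stop("raw layout requires `dims = c(height, width)`")
  bytes_px <- if (dtype == "uint16") 2L else 1L
  if (is.null(bit_depth)) bit_depth <- 8L * bytes_px
  fsz <- file.size(path) - header_skip
  frame_bytes <- prod(dims) * bytes_px
  if (fsz < frame_bytes || fsz %% frame_bytes != 0L)
    stop(sprintf("truncated stack: %d payload bytes is not a whole number of %d-byte frames",
                 fsz, frame_bytes))
  nf <- as.integer(fsz %/% frame_bytes)
  con <- file(path, "rb")
  on.exit(close(con))
  if (header_skip > 0) readBin(con, "raw", header_skip)
  v <- readBin(con, "integer", n = prod(dims) * nf, size = bytes_px,
               signed = FALSE, endian = "little")
  # raw frames are row-major within a frame (detector scan order):
  # value order is col fastest, so fill a W x H slab then transpose
  a <- array(v, c(dims[2], dims[1], nf))
  frame_stack(aperm(a, c(2, 1, 3)), bit_depth = bit_depth,
              frame_rate = frame_rate, source = path)
}

# -- MRC2014 (modes 0, 1, 2, 6) ----------------------------------------------

#' Read an MRC/MRCS stack
#'
#' Minimal MRC2014 reader supporting modes 0 (int8), 1 (int16), 2 (float32)
#' and 6 (uint16). The x axis of the file maps to columns, y to rows, z to
#' frames.
#'
#' @param path file to read.
#' @param frame_rate optional frames/second metadata.
#' @return a [frame_stack()].
#' @export
read_mrc <- function(path, frame_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- as.double(nx) * ny * nz
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "double", n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(v) < n) stop("truncated stack: MRC data section too short")
  if (mode == 2) {
    if (any(v != floor(v)) || any(v < 0))
      stop("float MRC with non-integral or negative values cannot form a frame_stack")
    v <- as.integer(v)
  }
  if (any(v < 0)) stop("negative pixel values in signed MRC are not supported")
  bit_depth <- switch(as.character(mode), "0" = 8L, "1" = 16L, "2" = 16L, "6" = 16L)
  a <- array(v, c(nx, ny, nz))
  frame_stack(aperm(a, c(2, 1, 3)), bit_depth = bit_depth,
              frame_rate = frame_rate, source = path)
}

#' Write a frame stack or 2-D image as MRC2014
#'
#' @param x a [frame_stack()], a 3-D integer array, or a 2-D matrix
#'   (e.g. a counted image).
#' @param path output file.
#' @param mode MRC mode: 0 (int8), 1 (int16), 2 (float32) or 6 (uint16).
#'   The default picks the smallest lossless unsigned-capable mode.
#' @return `path`, invisibly. Reading the file back yields the input values.
#' @export
write_mrc <- function(x, path, mode = NULL) {
  a <- if (inherits(x, "frame_stack")) x$frames else x
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (!is.array(a) || length(dim(a)) != 3L)
    stop("`x` must be a frame_stack, matrix or 3-D array")
  storage.mode(a) <- "integer"
  if (anyNA(a)) stop("NA values cannot be written")
  rng <- range(a)
  if (is.null(mode)) {
    mode <- if (rng[1] >= -128 && rng[2] <= 127) 0L
            else if (rng[2] <= 65535 && rng[1] >= 0) 6L
            else 2L
  }
  lim <- switch(as.character(mode),
    "0" = c(-128, 127), "1" = c(-32768, 32767), "2" = c(-Inf, Inf),
    "6" = c(0, 65535), stop("unsupported MRC mode: ", mode))
  if (rng[1] < lim[1] || rng[2] > lim[2])
    stop(sprintf("values [%d, %d] overflow MRC mode %d", rng[1], rng[2], mode))
  d <- dim(a)  # H, W, n
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(c(d[2], d[1], d[3], mode, 0L, 0L, 0L, d[2], d[1], d[3]))  # n*, mode, *start, m*
  wf(c(d[2], d[1], d[3], 90, 90, 90))                          # cella, cellb
  wi(c(1L, 2L, 3L))                                            # mapc/mapr/maps
  wf(c(rng[1], rng[2], mean(a)))                               # dmin/dmax/dmean
  wi(c(0L, 0L))                                                # ispg, nsymbt
  writeBin(raw(100), con)                                      # extra
  wf(c(0, 0, 0))                                               # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)             # LE machine stamp
  wf(stats::sd(a))
  wi(0L)                                                       # nlabl
  writeBin(raw(800), con)
  v <- as.vector(aperm(a, c(2, 1, 3)))                         # x fastest
  if (mode == 0L) {
    writeBin(v, con, size = 1)
  } else if (mode == 2L) {
    writeBin(as.double(v), con, size = 4, endian = "little")
  } else {
    if (mode == 6L) v <- ifelse(v > 32767L, v - 65536L, v)
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}

# -- calibration TIFF --------------------------------------------------------

# Threshold maps are persisted as single-page 32-bit float TIFFs. libtiff
# float storage is defined on [0, 1], so ADU values are scaled by 2^-17
# (thresholds of 16-bit data are < 2^16) and dead pixels (+Inf threshold)
# are stored as the sentinel 1.0.
.tiff_scale <- 2^17

#' Write a calibration frame to TIFF
#'
#' @param calib a [calibration_frame()].
#' @param path output TIFF for the threshold map.
#' @param sidecars if `TRUE`, also write `<path>.dark.tif` / `<path>.gain.tif`
#'   when dark/gain maps are present.
#' @return `path`, invisibly.
#' @export
write_calibration_tiff <- function(calib, path, sidecars = TRUE) {
  wmap <- function(m, p) {
    m <- m / .tiff_scale
    m[!is.finite(m)] <- 1.0
    tiff::writeTIFF(m, p, bits.per.sample = 32L, reduce = FALSE)
  }
  suppressWarnings(wmap(calib$threshold, path))
  if (sidecars && !is.null(calib$dark))
    suppressWarnings(wmap(calib$dark, paste0(path, ".dark.tif")))
  if (sidecars && !is.null(calib$gain))
    suppressWarnings(wmap(calib$gain, paste0(path, ".gain.tif")))
  invisible(path)
}

#' Read a calibration frame from TIFF
#'
#' @param path threshold-map TIFF written by [write_calibration_tiff()].
#' @param r false-positive-rate metadata to attach (not stored in the TIFF).
#' @return a [calibration_frame()]. Sidecar dark/gain TIFFs are picked up
#'   when present next to `path`.
#' @export
read_calibration_tiff <- function(path, r = pnorm(-3)) {
  rmap <- function(p) {
    m <- tiff::readTIFF(p)
    # the dead-pixel sentinel is 1.0; real thresholds scale to <= 0.5
    m[m >= 0.99] <- Inf
    m * .tiff_scale
  }
  thr <- rmap(path)
  dark <- if (file.exists(paste0(path, ".dark.tif"))) rmap(paste0(path, ".dark.tif"))
  gain <- if (file.exists(paste0(path, ".gain.tif"))) rmap(paste0(path, ".gain.tif"))
  calibration_frame(threshold = thr, dark = dark, gain = gain, r = r)
}
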