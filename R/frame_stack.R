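#' Movie-mode detector frame stack
#'
#' The in-memory container for dense movie-mode data: a cube of unsigned
#' integer detector frames together with the declared bit depth of the
#' digitizer. Frames are stored as an `H x W x n_frames` integer array in
#' acquisition order; pixel `(r, c)` of frame `i` is `frames[r, c, i]`
#' (1-based, row = slow detector axis).
#'
#' @param frames integer array `H x W x n_frames`, or a matrix for a single
#'   frame. All values must be non-negative and below `2^bit_depth`.
#' @param bit_depth integer, bits per pixel of the digitizer (1..16).
#' @param frame_rate optional frames per second (used only as metadata).
#' @param source provenance string.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, bit_depth = 16L, frame_rate = NULL,
                        source = "memory") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x n_frames array")
  if (is.double(frames)) {
    if (any(frames != floor(frames), na.rm = TRUE))
      stop("`frames` must hold integer pixel values")
    storage.mode(frames) <- "integer"
  }
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 16L)
    stop("`bit_depth` must be in 1..16")
  if (anyNA(frames)) stop("`frames` contains NA")
  rng <- range(frames)
  if (rng[1] < 0L) stop("pixel values must be non-negative")
  if (rng[2] >= 2^bit_depth)
    stop(sprintf("pixel value %d exceeds the declared %d-bit depth",
                 rng[2], bit_depth))
  structure(
    list(frames = frames, bit_depth = bit_depth,
         frame_rate = frame_rate, source = source),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d, %d-bit (source: %s)\n",
              d[3], d[1], d[2], x$bit_depth, x$source))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Frame dimensions of a stack
#' @param stack a [frame_stack()].
#' @return integer `c(height, width)`.
#' @export
frame_dims <- function(stack) dim(stack$frames)[1:2]

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param i frame number (1-based).
#' @return integer `H x W` matrix.
#' @export
get_frame <- function(stack, i) {
  n <- n_frames(stack)
  if (i < 1L || i > n) stop(sprintf("frame %d out of range 1..%d", i, n))
  m <- stack$frames[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}
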