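#' Threshold a frame into a binary signal map
#'
#' A pixel is signal iff its value is strictly greater than its calibrated
#' threshold (a pixel exactly at threshold is noise). Dead pixels (infinite
#' threshold) are never signal.
#'
#' @param frame integer `H x W` matrix.
#' @param calib a [calibration_frame()] (or a bare threshold matrix).
#' @return logical `H x W` mask, `TRUE` = signal.
#' @export
threshold_frame <- function(frame, calib) {
  thr <- if (inherits(calib, "calibration_frame")) calib$threshold else calib
  if (!identical(dim(frame), dim(thr)))
    stop("frame and calibration shapes do not match")
  frame > thr
}

# low-level C labeling: list(labels = integer matrix, n = count)
label_mask <- function(mask, connectivity = 8L, periodic = FALSE) {
  storage.mode(mask) <- "logical"
  res <- .Call(C_label_components, mask, nrow(mask), ncol(mask),
               as.integer(connectivity), isTRUE(periodic))
  list(labels = res[[1]], n = res[[2]])
}

#' Labeled electron puddles of a binary map
#'
#' Identifies the maximal connected clusters of signal pixels (electron
#' puddles) via two-pass union-find labeling. Labels are assigned in
#' row-major first-touch order, which also fixes the on-disk order of L2
#' summary statistics.
#'
#' @param mask logical `H x W` binary map.
#' @param frame optional integer frame; when given, per-puddle ADU values
#'   are attached (needed for intensity-based localization and statistics).
#' @param connectivity pixel adjacency, 8 (default, king moves) or 4.
#' @return a `puddle_set`: list with `labels` (integer matrix, 0 =
#'   background), `n`, `area`, `pixels` (per-puddle 2-column (row, col)
#'   matrices in row-major order), `values` (per-puddle ADUs or `NULL`) and
#'   `connectivity`.
#' @export
label_components <- function(mask, frame = NULL, connectivity = 8L) {
  lab <- label_mask(mask, connectivity)
  n <- lab$n
  H <- nrow(mask)
  idx <- which(mask)                    # column-major linear indices
  labs <- lab$labels[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  # row-major order within each puddle
  ord <- order(labs, rows, cols)
  pixels <- split_rows(cbind(rows, cols)[ord, , drop = FALSE], labs[ord], n)
  values <- if (!is.null(frame)) {
    if (!identical(dim(frame), dim(mask))) stop("frame and mask shapes differ")
    split(frame[idx][ord], factor(labs[ord], levels = seq_len(n)))
  }
  structure(list(labels = lab$labels, n = n,
                 area = as.integer(tabulate(labs, nbins = n)),
                 pixels = pixels, values = values,
                 connectivity = as.integer(connectivity)),
            class = "puddle_set")
}

split_rows <- function(m, f, n) {
  lapply(split(seq_len(nrow(m)), factor(f, levels = seq_len(n))),
         function(i) m[i, , drop = FALSE])
}

#' @export
print.puddle_set <- function(x, ...) {
  cat(sprintf("<puddle_set> %d puddle(s) on %d x %d map (%d-connectivity)%s\n",
              x$n, nrow(x$labels), ncol(x$labels), x$connectivity,
              if (is.null(x$values)) "" else ", with ADU values"))
  invisible(x)
}

# keep puddles `keep` (indices), relabel 1..length(keep) in original order
subset_puddles <- function(ps, keep) {
  keep <- sort(keep)
  new_labels <- ps$labels
  map <- integer(ps$n)
  map[keep] <- seq_along(keep)
  nz <- new_labels != 0L
  new_labels[nz] <- map[new_labels[nz]]
  structure(list(labels = new_labels, n = length(keep),
                 area = ps$area[keep],
                 pixels = ps$pixels[keep],
                 values = if (!is.null(ps$values)) ps$values[keep],
                 connectivity = ps$connectivity),
            class = "puddle_set")
}

#' Summary statistic of a puddle
#'
#' @param values ADU values of one puddle (non-empty), or a `puddle_set`
#'   with values attached (then all puddles are summarized).
#' @param statistic `"sum"`, `"max"` or `"mean"`. Means are rounded to the
#'   packed integer grid.
#' @return numeric scalar (or vector over puddles).
#' @export
summarize_puddle <- function(values, statistic = c("max", "sum", "mean")) {
  statistic <- match.arg(statistic)
  if (inherits(values, "puddle_set")) {
    if (is.null(values$values)) stop("puddle_set carries no ADU values")
    return(vapply(values$values, summarize_puddle, numeric(1),
                  statistic = statistic))
  }
  if (length(values) == 0L) stop("puddle is empty")
  switch(statistic,
         sum = sum(values),
         max = max(values),
         mean = round(mean(values)))
}

# round-half-down to a pixel: 2.5 -> 2
round_half_down <- function(x) ceiling(x - 0.5)

#' Localize a puddle to a single pixel
#'
#' Reduces a puddle to the estimated entry point of the incident electron,
#' by one of the three standard strategies. Centroids are rounded
#' half-down per axis, so a uniform 2 x 2 puddle maps to its top-left
#' pixel.
#'
#' @param pixels 2-column (row, col) matrix of the puddle's pixels, or a
#'   `puddle_set` (then all puddles are localized; returns an n x 2 matrix).
#' @param values ADU values matching `pixels` (required for the intensity
#'   strategies).
#' @param strategy `"max_pixel"` (brightest pixel), `"weighted_centroid"`
#'   (intensity-weighted center of mass) or `"unweighted_centroid"` (shape
#'   centroid; the only strategy available without intensities, i.e. from
#'   L2/L3 data).
#' @return integer `c(row, col)` (or matrix over puddles).
#' @export
localize_puddle <- function(pixels, values = NULL,
                            strategy = c("unweighted_centroid",
                                         "weighted_centroid", "max_pixel")) {
  strategy <- match.arg(strategy)
  if (inherits(pixels, "puddle_set")) {
    ps <- pixels
    out <- vapply(seq_len(ps$n), function(i)
      localize_puddle(ps$pixels[[i]], ps$values[[i]], strategy),
      integer(2))
    return(t(out))
  }
  if (nrow(pixels) == 0L) stop("puddle is empty")
  if (strategy == "unweighted_centroid")
    return(as.integer(round_half_down(colMeans(pixels))))
  if (is.null(values))
    stop(sprintf("strategy '%s' requires ADU values (L1-sourced data)", strategy))
  if (strategy == "max_pixel")
    return(as.integer(pixels[which.max(values), ]))
  w <- values / sum(values)
  as.integer(round_half_down(colSums(pixels * w)))
}

# -- bit packing -------------------------------------------------------------

#' Pack unsigned integers into a dense bit string
#'
#' Concatenates the low `bit_depth` bits of every value, LSB-first, into
#' `ceiling(n * bit_depth / 8)` bytes. [unpack_bits()] is the exact inverse.
#'
#' @param values non-negative integers, each `< 2^bit_depth`.
#' @param bit_depth bits per value (1..32).
#' @return raw vector.
#' @export
pack_bits <- function(values, bit_depth) {
  .Call(C_pack_bits, as.integer(values), as.integer(bit_depth))
}

#' @rdname pack_bits
#' @param bytes raw vector produced by [pack_bits()].
#' @param n number of values to unpack.
#' @export
unpack_bits <- function(bytes, bit_depth, n) {
  .Call(C_unpack_bits, bytes, as.integer(bit_depth), as.double(n))
}

# binary map <-> packed bytes, row-major pixel order, LSB-first
mask_to_bytes <- function(mask) pack_bits(as.integer(t(mask)), 1L)

bytes_to_mask <- function(bytes, dims) {
  n <- prod(dims)
  if (length(bytes) != ceiling(n / 8))
    stop("corrupted payload: binary map has ", length(bytes),
         " bytes, expected ", ceiling(n / 8))
  v <- unpack_bits(bytes, 1L, n)
  matrix(as.logical(v), dims[1], dims[2], byrow = TRUE)
}

# -- reduced frames ----------------------------------------------------------

# packed width of an L2 statistic: max/mean fit the input depth; sums may
# need headroom for the largest puddle (area capped at 256 pixels)
l2_stat_depth <- function(statistic, bit_depth) {
  if (statistic == "sum") bit_depth + 8L else bit_depth
}

#' Reduce one frame to a given reduction level
#'
#' The four reduction levels share the thresholding step and retain
#' progressively less information:
#' * **L1** - binary map + bit-packed ADUs of all signal pixels (row-major
#'   order); lossless for supra-threshold signal, supports post-hoc
#'   recalibration and any counting strategy.
#' * **L2** - binary map + one packed summary statistic per puddle (in
#'   label order).
#' * **L3** - binary map only.
#' * **L4** - binary map of one localization pixel per puddle (the counted
#'   frame).
#'
#' L1 stores the original (not dark-subtracted) ADUs so the data can be
#' recalibrated after acquisition.
#'
#' @param frame integer `H x W` matrix.
#' @param calib a [calibration_frame()] or threshold matrix.
#' @param level 1, 2, 3 or 4.
#' @param statistic L2 summary statistic (`"max"`, `"sum"`, `"mean"`).
#' @param strategy L4 localization strategy (see [localize_puddle()]).
#' @param bit_depth packed bits per ADU (defaults to the calibration's data
#'   bit depth, or 16).
#' @param connectivity puddle connectivity for L2/L4.
#' @return an object of class `reduced_frame`.
#' @export
reduce_frame <- function(frame, calib, level,
                         statistic = c("max", "sum", "mean"),
                         strategy = c("unweighted_centroid",
                                      "weighted_centroid", "max_pixel"),
                         bit_depth = 16L, connectivity = 8L) {
  statistic <- match.arg(statistic)
  strategy <- match.arg(strategy)
  if (!level %in% 1:4) stop("invalid reduction level: ", level)
  level <- as.integer(level)
  mask <- threshold_frame(frame, calib)
  dims <- dim(mask)
  n_signal <- sum(mask)
  n_puddles <- NA_integer_
  intensity <- NULL
  out_mask <- mask
  if (level == 1L) {
    vals <- t(frame)[t(mask)]           # row-major signal order
    intensity <- pack_bits(vals, bit_depth)
  } else if (level == 2L) {
    ps <- label_components(mask, frame, connectivity)
    n_puddles <- ps$n
    sbd <- l2_stat_depth(statistic, bit_depth)
    stats <- pmin(summarize_puddle(ps, statistic), 2^sbd - 1)
    intensity <- pack_bits(stats, sbd)
  } else if (level == 4L) {
    ps <- label_components(mask, frame, connectivity)
    n_puddles <- ps$n
    out_mask <- matrix(FALSE, dims[1], dims[2])
    if (ps$n > 0L) {
      loc <- localize_puddle(ps, strategy = strategy)
      out_mask[loc] <- TRUE
    }
    n_signal <- sum(out_mask)
  }
  structure(list(level = level, dims = dims, bit_depth = as.integer(bit_depth),
                 binary_payload = mask_to_bytes(out_mask),
                 intensity_payload = intensity,
                 n_signal = as.integer(n_signal), n_puddles = n_puddles,
                 statistic = statistic, strategy = strategy,
                 connectivity = as.integer(connectivity)),
            class = "reduced_frame")
}

#' @export
print.reduced_frame <- function(x, ...) {
  cat(sprintf("<reduced_frame> L%d, %d x %d, %d signal pixel(s)%s, payload %d + %d bytes\n",
              x$level, x$dims[1], x$dims[2], x$n_signal,
              if (is.na(x$n_puddles)) "" else sprintf(", %d puddle(s)", x$n_puddles),
              length(x$binary_payload), length(x$intensity_payload)))
  invisible(x)
}

#' Expand a reduced frame back to its fullest representation
#'
#' The exact inverse of [reduce_frame()] up to the level's declared
#' information loss. Sub-threshold pixels come back as 0.
#'
#' @param reduced a `reduced_frame`.
#' @return L1: sparse integer frame (signal ADUs, 0 elsewhere). L2: list
#'   with `mask`, `labels` and per-puddle `statistics` (label order). L3:
#'   the logical binary map. L4: integer counted map (1 at each event
#'   pixel).
#' @export
expand_frame <- function(reduced) {
  dims <- reduced$dims
  mask <- bytes_to_mask(reduced$binary_payload, dims)
  n_true <- sum(mask)
  lvl <- reduced$level
  if (lvl == 3L) return(mask)
  if (lvl == 4L) return(matrix(as.integer(mask), dims[1], dims[2]))
  if (lvl == 1L) {
    if (n_true != reduced$n_signal)
      stop("corrupted payload: binary map has ", n_true,
           " signal pixels, header says ", reduced$n_signal)
    expect <- as.integer(ceiling(n_true * reduced$bit_depth / 8))
    if (length(reduced$intensity_payload) != expect)
      stop("corrupted payload: intensity payload has ",
           length(reduced$intensity_payload), " bytes, expected ", expect)
    vals <- unpack_bits(reduced$intensity_payload, reduced$bit_depth, n_true)
    out <- matrix(0L, dims[2], dims[1])   # build transposed for row-major fill
    out[t(mask)] <- vals
    return(t(out))
  }
  # L2
  ps <- label_components(mask, connectivity = reduced$connectivity)
  if (!is.na(reduced$n_puddles) && ps$n != reduced$n_puddles)
    stop("corrupted payload: found ", ps$n, " puddles, header says ",
         reduced$n_puddles)
  sbd <- l2_stat_depth(reduced$statistic, reduced$bit_depth)
  expect <- as.integer(ceiling(ps$n * sbd / 8))
  if (length(reduced$intensity_payload) != expect)
    stop("corrupted payload: statistic payload has ",
         length(reduced$intensity_payload), " bytes, expected ", expect)
  stats <- unpack_bits(reduced$intensity_payload, sbd, ps$n)
  list(mask = mask, labels = ps$labels, statistics = stats)
}

# -- centroid encodings ------------------------------------------------------

#' Encode a set of centroids
#'
#' Three interchangeable encodings of a centroid set: `"linear_index"`
#' (each centroid as one 2n-bit 0-based row-major linear index, n = input
#' bit depth), `"rle"` (sorted linear indices, gap/run encoded as LEB128
#' varints) and `"binary_image"` (a packed binary map, as used by L4; the
#' default in practice since it needs no sorting).
#'
#' @param centroids 2-column 1-based (row, col) matrix; duplicates are
#'   merged.
#' @param dims frame `c(height, width)`.
#' @param mode one of `"binary_image"`, `"linear_index"`, `"rle"`.
#' @param bit_depth input data bit depth, fixing the linear-index width to
#'   `2 * bit_depth` bits; `2^(2 * bit_depth)` must cover `prod(dims)`.
#' @return raw payload; the empty set encodes as a zero-length payload in
#'   every mode.
#' @export
encode_centroids <- function(centroids, dims,
                             mode = c("binary_image", "linear_index", "rle"),
                             bit_depth = 8L) {
  mode <- match.arg(mode)
  centroids <- unique(round(centroids))
  if (nrow(centroids) == 0L) return(raw(0))
  if (any(centroids[, 1] < 1 | centroids[, 1] > dims[1] |
          centroids[, 2] < 1 | centroids[, 2] > dims[2]))
    stop("centroid out of frame bounds")
  idx0 <- (centroids[, 1] - 1L) * dims[2] + (centroids[, 2] - 1L)  # 0-based row-major
  if (mode == "binary_image") {
    m <- matrix(FALSE, dims[1], dims[2])
    m[as.matrix(centroids)] <- TRUE
    return(mask_to_bytes(m))
  }
  if (mode == "linear_index") {
    w <- 2L * bit_depth
    if (prod(dims) > 2^w)
      stop(sprintf("2n-bit linear index (n = %d) cannot address %d pixels",
                   bit_depth, prod(dims)))
    return(pack_bits(idx0, w))
  }
  # rle: sorted indices, first value then successive gaps, LEB128 varints
  s <- sort(idx0)
  deltas <- c(s[1], diff(s))
  encode_varints(deltas)
}

#' @rdname encode_centroids
#' @param payload raw payload produced by [encode_centroids()].
#' @param n for `"linear_index"`: centroid count if the payload length is
#'   ambiguous (widths below 8 bits); usually inferred.
#' @return for `decode_centroids`: sorted (row-major) 2-column 1-based
#'   (row, col) matrix.
#' @export
decode_centroids <- function(payload, dims,
                             mode = c("binary_image", "linear_index", "rle"),
                             bit_depth = 8L, n = NULL) {
  mode <- match.arg(mode)
  if (length(payload) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (mode == "binary_image") {
    m <- bytes_to_mask(payload, dims)
    idx0 <- sort((which(t(m)) - 1L))
  } else if (mode == "linear_index") {
    w <- 2L * bit_depth
    if (is.null(n)) n <- (length(payload) * 8L) %/% w
    idx0 <- sort(unpack_bits(payload, w, n))
  } else {
    idx0 <- cumsum(decode_varints(payload))
  }
  out <- cbind(row = idx0 %/% dims[2] + 1L, col = idx0 %% dims[2] + 1L)
  storage.mode(out) <- "integer"
  out
}

encode_varints <- function(x) {
  out <- raw(0)
  chunks <- lapply(x, function(v) {
    b <- raw(0)
    repeat {
      lo <- v %% 128L
      v <- v %/% 128L
      b <- c(b, as.raw(lo + if (v > 0) 128L else 0L))
      if (v == 0L) break
    }
    b
  })
  do.call(c, chunks)
}

decode_varints <- function(bytes) {
  vals <- integer(0)
  v <- 0L; shift <- 0L
  for (b in as.integer(bytes)) {
    v <- v + (b %% 128L) * 2L^shift
    if (b < 128L) {
      vals <- c(vals, v)
      v <- 0L; shift <- 0L
    } else {
      shift <- shift + 7L
    }
  }
  if (shift != 0L) stop("corrupted varint stream (truncated)")
  vals
}
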