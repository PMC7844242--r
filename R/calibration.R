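#' Per-pixel signal/noise calibration frame
#'
#' Holds the per-pixel ADU thresholds that separate electron signal from
#' readout/thermal noise, plus optional per-pixel dark-level and gain maps.
#' Dead pixels carry an infinite threshold and therefore never produce
#' signal.
#'
#' @param threshold numeric `H x W` matrix of ADU thresholds (`Inf` = dead).
#' @param dark optional per-pixel dark level map (ADU).
#' @param gain optional per-pixel gain map (ADU per electron, relative).
#' @param r tolerable false-positive rate used to derive the thresholds,
#'   in `(0, 0.5]`.
#' @param n_calibration_frames number of frames behind the calibration
#'   (metadata).
#' @return an object of class `calibration_frame`.
#' @export
calibration_frame <- function(threshold, dark = NULL, gain = NULL,
                              r = pnorm(-3), n_calibration_frames = NA_integer_) {
  if (!is.matrix(threshold)) stop("`threshold` must be a matrix")
  if (!is.null(dark)) {
    if (!identical(dim(dark), dim(threshold)))
      stop("`dark` and `threshold` must share one shape")
    bad <- is.finite(threshold) & is.finite(dark) & threshold < dark
    if (any(bad))
      stop(sprintf("%d pixel(s) have threshold below dark level", sum(bad)))
  }
  if (!is.null(gain) && !identical(dim(gain), dim(threshold)))
    stop("`gain` and `threshold` must share one shape")
  if (!is.numeric(r) || r <= 0 || r > 0.5)
    stop("`r` must be a false-positive rate in (0, 0.5]")
  structure(
    list(threshold = threshold, dark = dark, gain = gain, r = r,
         n_calibration_frames = as.integer(n_calibration_frames)),
    class = "calibration_frame")
}

#' @export
print.calibration_frame <- function(x, ...) {
  fin <- is.finite(x$threshold)
  cat(sprintf("<calibration_frame> %d x %d, r = %.4g, threshold range [%.4g, %.4g], %d dead pixel(s)\n",
              nrow(x$threshold), ncol(x$threshold), x$r,
              min(x$threshold[fin]), max(x$threshold[fin]), sum(!fin)))
  invisible(x)
}

#' Estimate the global signal/noise threshold from dark samples
#'
#' Fits a normal distribution to sampled dark ADU values and returns the
#' `(1 - r)` quantile: a pixel exceeding this threshold is a false positive
#' with probability `r` under the fitted dark model.
#'
#' @param dark_values numeric sample of dark ADUs (at least 2 values).
#' @param r tolerable false-positive rate in `(0, 0.5]`. Alternatively pass
#'   `sigma` to use a one-sided sigma-multiple (r of `pnorm(-sigma)`).
#' @param sigma optional sigma-multiple overriding `r` (e.g. `3` or `4`).
#' @param robust if `TRUE`, use median/MAD instead of mean/SD.
#' @return the ADU threshold (scalar).
#' @export
estimate_global_threshold <- function(dark_values, r = pnorm(-3), sigma = NULL,
                                      robust = FALSE) {
  if (!is.null(sigma)) r <- pnorm(-sigma)
  if (length(dark_values) < 2L) stop("need at least 2 dark samples")
  if (any(!is.finite(dark_values))) stop("dark samples must be finite")
  if (r <= 0 || r > 0.5) stop("`r` must be in (0, 0.5]")
  if (robust) {
    mu <- median(dark_values); s <- mad(dark_values)
  } else {
    mu <- mean(dark_values); s <- sd(dark_values)
  }
  mu + qnorm(1 - r) * s
}

#' Per-pixel dark levels of a calibration stack
#'
#' At calibration dose rates a pixel sees an electron in only a small
#' fraction of frames, so its median across frames is effectively its dark
#' level. A mean mode is offered for speed, at a slightly higher
#' false-positive rate.
#'
#' @param calib_stack a [frame_stack()] of flat-field low-dose frames.
#' @param method `"median"` (robust, default) or `"mean"`.
#' @return numeric `H x W` dark-level map.
#' @export
pixel_dark_levels <- function(calib_stack, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- calib_stack$frames
  if (dim(f)[3] == 1L) {
    warning("single-frame calibration stack: returning the frame itself")
    return(get_frame(calib_stack, 1L) * 1.0)
  }
  if (method == "mean") return(rowMeans(f, dims = 2))
  apply(f, c(1, 2), median)
}

#' Per-pixel gains of a calibration stack
#'
#' If the calibration set delivered a total dose of `total_dose` electrons
#' per pixel, small enough that double hits on one pixel are negligible,
#' then a pixel's gain is the median of its `ceiling(total_dose)` largest
#' dark-subtracted intensities across frames.
#'
#' @param calib_stack a [frame_stack()].
#' @param total_dose total electrons per pixel in the calibration set (N).
#' @param dark optional per-pixel dark map to subtract (default: per-pixel
#'   median via [pixel_dark_levels()]).
#' @return numeric `H x W` gain map (ADU per electron).
#' @export
pixel_gains <- function(calib_stack, total_dose, dark = NULL) {
  nf <- n_frames(calib_stack)
  if (total_dose < 1) stop("`total_dose` must be at least 1 electron/pixel")
  k <- as.integer(ceiling(total_dose))
  if (k >= nf) stop("total_dose must be smaller than the number of calibration frames")
  if (is.null(dark)) dark <- pixel_dark_levels(calib_stack)
  f <- sweep(calib_stack$frames, c(1, 2), dark)
  apply(f, c(1, 2), function(t) {
    top <- sort.int(t, decreasing = TRUE)[seq_len(k)]
    median(top)
  })
}

#' Dose estimate from randomly placed patches
#'
#' @param dose_per_pixel mean electrons/pixel over the calibration set.
#' @param n_c per-patch electron counts.
#' @param n_patches,patch_size patch geometry used.
#' @return an object of class `dose_estimate`.
#' @export
dose_estimate <- function(dose_per_pixel, n_c, n_patches, patch_size) {
  stopifnot(dose_per_pixel >= 0, n_patches >= 1)
  structure(list(dose_per_pixel = dose_per_pixel, n_c = n_c,
                 n_patches = n_patches, patch_size = patch_size),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose_estimate> %.4g e-/pixel (%d patches of %d x %d, SE %.3g)\n",
              x$dose_per_pixel, x$n_patches, x$patch_size, x$patch_size,
              sd(x$n_c) / sqrt(length(x$n_c))))
  invisible(x)
}

#' Estimate total dose per pixel from a calibration stack
#'
#' Places small 2-D patches at random positions; within each patch,
#' per-pixel thresholds are fitted from that pixel's own trace (normal fit
#' at false-positive rate `r`), frames are thresholded and
#' connected-components labeled, and components whose maximum-value pixel
#' sits at the patch centre are counted as electron events emanating from
#' the central pixel. The mean count across patches estimates the total
#' dose per pixel in the calibration set.
#'
#' @param calib_stack a [frame_stack()].
#' @param r per-pixel false-positive rate for the patch thresholds.
#' @param n_patches number of randomly placed patches.
#' @param patch_size odd patch edge length in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @param seed optional RNG seed for patch placement.
#' @return a [dose_estimate()].
#' @export
estimate_dose_per_pixel <- function(calib_stack, r = pnorm(-3), n_patches = 64L,
                                    patch_size = 11L, connectivity = 8L,
                                    seed = NULL) {
  d <- frame_dims(calib_stack)
  if (patch_size %% 2L != 1L) stop("`patch_size` must be odd so a central pixel exists")
  if (patch_size > min(d)) stop("patch larger than frame")
  nf <- n_frames(calib_stack)
  half <- (patch_size - 1L) %/% 2L
  pick <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  centres <- with_seed(seed, cbind(
    pick(seq.int(1L + half, d[1] - half), n_patches),
    pick(seq.int(1L + half, d[2] - half), n_patches)))
  mid <- half + 1L
  n_c <- vapply(seq_len(n_patches), function(p) {
    rows <- (centres[p, 1] - half):(centres[p, 1] + half)
    cols <- (centres[p, 2] - half):(centres[p, 2] + half)
    patch <- calib_stack$frames[rows, cols, , drop = FALSE]
    thr <- apply(patch, c(1, 2), function(t) mean(t) + qnorm(1 - r) * sd(t))
    cnt <- 0L
    for (i in seq_len(nf)) {
      fr <- patch[, , i]
      mask <- fr > thr
      if (!any(mask)) next
      lab <- label_mask(mask, connectivity)
      centre_lab <- lab$labels[mid, mid]
      if (centre_lab == 0L) next
      px <- which(lab$labels == centre_lab)
      centre_idx <- mid + (mid - 1L) * patch_size
      # a puddle emanates from its maximum-value pixel
      if (px[which.max(fr[px])] == centre_idx) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  dose_estimate(mean(n_c), n_c, n_patches, patch_size)
}

#' Build the per-pixel calibration frame
#'
#' Adapts a single global threshold to every pixel: the global threshold is
#' shifted so the pixel's dark level matches the global mean dark level and
#' scaled so the pixel's gain matches the global gain:
#' `threshold_p = dark_p + (global_threshold - global_dark_mean) * gain_p / global_gain`.
#' Pixels with non-positive gain are flagged dead (`Inf` threshold).
#'
#' @param global_threshold global ADU threshold (from
#'   [estimate_global_threshold()]).
#' @param global_dark_mean global mean dark level (ADU).
#' @param global_gain global gain (ADU per electron).
#' @param dark per-pixel dark map.
#' @param gain per-pixel gain map.
#' @param r false-positive rate metadata.
#' @param n_calibration_frames metadata.
#' @return a [calibration_frame()].
#' @export
build_calibration_frame <- function(global_threshold, global_dark_mean,
                                    global_gain, dark, gain, r = pnorm(-3),
                                    n_calibration_frames = NA_integer_) {
  if (global_gain <= 0) stop("`global_gain` must be strictly positive")
  thr <- dark + (global_threshold - global_dark_mean) * (gain / global_gain)
  thr[gain <= 0] <- Inf
  calibration_frame(thr, dark = dark, gain = gain, r = r,
                    n_calibration_frames = n_calibration_frames)
}

#' Fast on-the-fly calibration of a flat-field stack
#'
#' Convenience wrapper chaining [pixel_dark_levels()],
#' [estimate_dose_per_pixel()], [pixel_gains()],
#' [estimate_global_threshold()] and [build_calibration_frame()].
#'
#' @param calib_stack a [frame_stack()] of flat-field low-dose frames.
#' @param r false-positive rate (or pass `sigma`).
#' @param sigma optional sigma-multiple overriding `r`.
#' @param n_patches,patch_size dose-estimation patch geometry.
#' @param dark_method `"median"` or `"mean"`.
#' @param seed RNG seed for patch placement.
#' @return a [calibration_frame()].
#' @export
calibrate_on_the_fly <- function(calib_stack, r = pnorm(-3), sigma = NULL,
                                 n_patches = 64L, patch_size = 11L,
                                 dark_method = "median", seed = NULL) {
  if (!is.null(sigma)) r <- pnorm(-sigma)
  dark <- pixel_dark_levels(calib_stack, method = dark_method)
  ds <- sweep(calib_stack$frames, c(1, 2), dark)
  gthr_excess <- estimate_global_threshold(as.vector(ds), r = r)
  dose <- estimate_dose_per_pixel(calib_stack, r = r, n_patches = n_patches,
                                  patch_size = patch_size, seed = seed)
  total <- max(1, dose$dose_per_pixel)
  gain <- pixel_gains(calib_stack, total_dose = total, dark = dark)
  ggain <- median(gain)
  gdark <- mean(dark)
  build_calibration_frame(gdark + gthr_excess, gdark, ggain, dark, gain, r = r,
                          n_calibration_frames = n_frames(calib_stack))
}

#' Common-mode correction of one frame
#'
#' Detector readout groups (blocks of `block_shape` pixels, 4 x 256 on the
#' reference detector) share a correlated thermal offset. The offset of each
#' block is estimated as the median dark-subtracted value of its non-signal
#' pixels and subtracted from the block.
#'
#' @param frame integer `H x W` matrix.
#' @param calib a [calibration_frame()] supplying the dark map (zero if
#'   absent) and the thresholds used to exclude signal pixels from the
#'   offset estimate.
#' @param block_shape integer `c(rows, cols)` of one readout block; edge
#'   blocks take the remainder.
#' @return corrected numeric frame (same shape).
#' @export
common_mode_correct <- function(frame, calib, block_shape = c(4L, 256L)) {
  d <- dim(frame)
  dark <- if (is.null(calib$dark)) 0 else calib$dark
  ds <- frame - dark
  out <- ds
  row_starts <- seq.int(1L, d[1], by = block_shape[1])
  col_starts <- seq.int(1L, d[2], by = block_shape[2])
  for (r0 in row_starts) {
    for (c0 in col_starts) {
      rows <- r0:min(r0 + block_shape[1] - 1L, d[1])
      cols <- c0:min(c0 + block_shape[2] - 1L, d[2])
      blk <- ds[rows, cols]
      noise <- frame[rows, cols] <= calib$threshold[rows, cols]
      if (!any(noise)) {
        warning(sprintf("block at (%d, %d) has no noise pixels; offset left at 0", r0, c0))
        offset <- 0
      } else {
        offset <- median(blk[noise])
      }
      out[rows, cols] <- blk - offset
    }
  }
  out + dark
}

#' Filter puddles by area
#'
#' Retains puddles whose pixel count lies in `[min_area, max_area]`; used by
#' the fine calibration to suppress false-positive detections (and, with
#' `min_area = 2`, to drop single-pixel puddles before gain re-estimation).
#'
#' @param puddles a `puddle_set` from [label_components()].
#' @param max_area largest retained area (pixels).
#' @param min_area smallest retained area (default 1).
#' @return a `puddle_set` containing only the surviving puddles,
#'   relabeled 1..n in the original label order.
#' @export
area_filter <- function(puddles, max_area = Inf, min_area = 1L) {
  if (max_area < min_area || min_area < 1L)
    stop("need max_area >= min_area >= 1")
  keep <- which(puddles$area >= min_area & puddles$area <= max_area)
  subset_puddles(puddles, keep)
}
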