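#' Enumerate fixed polyplets
#'
#' All translation-distinct clusters of `size` pixels connected under
#' 8-connectivity (king moves); rotations and reflections are counted as
#' distinct shapes. Used to catalogue electron puddle footprints (there
#' are, e.g., 110 fixed polyplets of four pixels).
#'
#' @param size pixel count, 1..8.
#' @return list with `shapes` (list of 2-column dr/dc offset matrices,
#'   normalized so min row = min col = 0, rows sorted row-major) and
#'   `count`.
#' @export
enumerate_fixed_polyplets <- function(size) {
  if (size < 1L || size > 8L) stop("`size` must be in 1..8")
  canon <- function(m) {
    m[, 1] <- m[, 1] - min(m[, 1])
    m[, 2] <- m[, 2] - min(m[, 2])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  key <- function(m) paste(m[, 1], m[, 2], sep = ",", collapse = ";")
  nbr <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  nbr <- nbr[!(nbr[, 1] == 0 & nbr[, 2] == 0), ]
  shapes <- list(matrix(0L, 1, 2, dimnames = list(NULL, c("dr", "dc"))))
  for (s in seq_len(size)[-1]) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    nxt <- list()
    for (sh in shapes) {
      have <- paste(sh[, 1], sh[, 2], sep = ",")
      for (i in seq_len(nrow(sh))) {
        cand <- cbind(sh[i, 1] + nbr[, 1], sh[i, 2] + nbr[, 2])
        new_cells <- !(paste(cand[, 1], cand[, 2], sep = ",") %in% have)
        for (j in which(new_cells)) {
          m <- canon(rbind(sh, cand[j, ]))
          k <- key(m)
          if (!exists(k, envir = seen, inherits = FALSE)) {
            assign(k, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- m
          }
        }
      }
    }
    shapes <- nxt
  }
  shapes <- lapply(shapes, function(m) {
    storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, c("dr", "dc"))
    m
  })
  list(shapes = shapes, count = length(shapes))
}

# canonical translation-only key of a pixel cluster
shape_key <- function(pix) {
  pix[, 1] <- pix[, 1] - min(pix[, 1])
  pix[, 2] <- pix[, 2] - min(pix[, 2])
  pix <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
  paste(pix[, 1], pix[, 2], sep = ",", collapse = ";")
}

new_loss_estimate <- function(dose_rate, method, loss, se, events, components,
                              n_frames, dims, connectivity, seed) {
  structure(list(dose_rate = dose_rate, method = method, loss = loss,
                 standard_error = se, events = events,
                 components = components, n_frames = n_frames, dims = dims,
                 connectivity = connectivity, seed = seed),
            class = "coincidence_loss_estimate")
}

#' @export
print.coincidence_loss_estimate <- function(x, ...) {
  cat(sprintf("<coincidence_loss> %.4g at %.4g e-/pixel/frame (%s, SE %.2g)\n",
              x$loss, x$dose_rate, x$method, x$standard_error))
  invisible(x)
}

# ratio-estimator standard error of (sum d) / (sum k) over frames
ratio_se <- function(d, k) {
  n <- length(k)
  K <- sum(k)
  if (n < 2L || K == 0) return(NA_real_)
  R <- sum(d) / K
  e <- d - R * k
  sqrt(n / (n - 1) * sum(e^2)) / K
}

#' Coincidence loss by simulation
#'
#' Simulates noiseless binary stamping of Poisson electron arrivals,
#' labels the connected components, and estimates the coincidence loss as
#' `1 - components / incident electrons`: electrons landing on one pixel
#' or within one 8-connected cluster are counted as a single merged event.
#'
#' At very low expected events per frame a distributionally identical
#' sparse path is used: rather than rasterizing frames, events are linked
#' whenever their stamped footprints overlap or touch (union-find over the
#' event adjacency graph), which gives the same component counts as
#' labeling the rasterized frame.
#'
#' @param dose_rate electron flux, e/pixel/frame (> 0).
#' @param shapes a [shape_library()].
#' @param dims frame shape (default 1024 x 1024).
#' @param n_frames frames to simulate.
#' @param connectivity 8 (default) or 4.
#' @param boundary `"periodic"` (default; removes edge bias) or `"clip"`.
#' @param seed RNG seed.
#' @param method `"auto"`, `"dense"` or `"sparse"`.
#' @return a `coincidence_loss_estimate` (loss, ratio-estimator standard
#'   error, totals).
#' @export
coincidence_loss_simulated <- function(dose_rate, shapes = shape_library("fixed_1px"),
                                       dims = c(1024L, 1024L), n_frames = 100L,
                                       connectivity = 8L,
                                       boundary = "periodic", seed = NULL,
                                       method = c("auto", "dense", "sparse")) {
  method <- match.arg(method)
  if (dose_rate <= 0) stop("`dose_rate` must be > 0")
  if (method == "auto")
    method <- if (dose_rate * prod(dims) < 64) "sparse" else "dense"
  with_seed(seed, {
    npx <- prod(dims)
    k <- rpois(n_frames, dose_rate * npx)
    comps <- integer(n_frames)
    if (method == "dense") {
      for (i in seq_len(n_frames)) {
        if (k[i] == 0L) next
        rows <- sample.int(dims[1], k[i], replace = TRUE)
        cols <- sample.int(dims[2], k[i], replace = TRUE)
        sid <- sample.int(length(shapes$offsets), k[i], replace = TRUE,
                          prob = shapes$prob)
        mask <- stamp_events(rows, cols, sid, shapes, dims, boundary)
        comps[i] <- label_mask(mask, connectivity,
                               periodic = boundary == "periodic")$n
      }
    } else {
      pairsets <- shape_pair_displacements(shapes, connectivity)
      reach <- pairsets$reach
      for (i in seq_len(n_frames)) {
        if (k[i] == 0L) next
        if (k[i] == 1L) { comps[i] <- 1L; next }
        rows <- sample.int(dims[1], k[i], replace = TRUE)
        cols <- sample.int(dims[2], k[i], replace = TRUE)
        sid <- sample.int(length(shapes$offsets), k[i], replace = TRUE,
                          prob = shapes$prob)
        comps[i] <- sparse_components(rows, cols, sid, pairsets, dims,
                                      boundary)
      }
    }
    loss <- 1 - sum(comps) / sum(k)
    new_loss_estimate(dose_rate, paste0("simulated_", method), loss,
                      ratio_se(k - comps, k), sum(k), sum(comps),
                      n_frames, dims, connectivity, seed)
  })
}

# For every ordered shape pair, the set of anchor displacements at which
# the two stamped footprints overlap or are adjacent under the given
# connectivity. Keys are delta_r * 4096 + delta_c (offset by 2048).
shape_pair_displacements <- function(shapes, connectivity = 8L) {
  L <- length(shapes$offsets)
  dil <- if (connectivity == 8L) as.matrix(expand.grid(-1:1, -1:1))
         else rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  keyfun <- function(dr, dc) (dr + 2048) * 4096 + (dc + 2048)
  sets <- vector("list", L * L)
  reach <- 0L
  for (a in seq_len(L)) {
    oa <- shapes$offsets[[a]]
    # dilate footprint a
    da <- unique(cbind(rep(oa[, 1], each = nrow(dil)) + rep.int(dil[, 1], nrow(oa)),
                       rep(oa[, 2], each = nrow(dil)) + rep.int(dil[, 2], nrow(oa))))
    for (b in seq_len(L)) {
      ob <- shapes$offsets[[b]]
      # displacements delta with (ob + delta) intersecting dilated oa
      dr <- rep(da[, 1], each = nrow(ob)) - rep.int(ob[, 1], nrow(da))
      dc <- rep(da[, 2], each = nrow(ob)) - rep.int(ob[, 2], nrow(da))
      sets[[(a - 1L) * L + b]] <- unique(keyfun(dr, dc))
      reach <- max(reach, max(abs(dr)), max(abs(dc)))
    }
  }
  list(sets = sets, L = L, reach = reach, keyfun = keyfun)
}

# component count of one frame's events from pairwise footprint adjacency
sparse_components <- function(rows, cols, sid, pairsets, dims, boundary) {
  k <- length(rows)
  dr <- outer(rows, rows, "-")
  dc <- outer(cols, cols, "-")
  if (boundary == "periodic") {
    dr <- dr - round(dr / dims[1]) * dims[1]
    dc <- dc - round(dc / dims[2]) * dims[2]
  }
  cand <- which(abs(dr) <= pairsets$reach & abs(dc) <= pairsets$reach &
                  upper.tri(dr), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(k)
  parent <- seq_len(k)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  L <- pairsets$L
  for (e in seq_len(nrow(cand))) {
    i <- cand[e, 1]; j <- cand[e, 2]
    set <- pairsets$sets[[(sid[i] - 1L) * L + sid[j]]]
    if (pairsets$keyfun(dr[j, i], dc[j, i]) %in% set) {
      ri <- findp(i); rj <- findp(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  sum(vapply(seq_len(k), findp, 0L) == seq_len(k))
}

#' Coincidence loss from a puddle size distribution (analytic)
#'
#' Closed-form estimate treating puddles as square bounding boxes of their
#' sampled size: two boxes of sides `a` and `b` merge under 8-connectivity
#' when their anchor displacement falls in an `(a + b + 1)^2` neighborhood,
#' so the counted rate is thinned to `dose_rate * exp(-dose_rate * E[A])`
#' with `E[A]` the expected merge-neighborhood area over two independent
#' size draws. A deliberately coarse model: it needs only the size
#' histogram (no shapes) and overestimates merging for non-square puddles.
#'
#' @param dose_rate electron flux, e/pixel/frame.
#' @param size_distribution probabilities over puddle areas `1..K`
#'   (normalized internally).
#' @return a `coincidence_loss_estimate` with `method = "analytic_size_dist"`.
#' @export
coincidence_loss_analytic <- function(dose_rate, size_distribution) {
  p <- size_distribution / sum(size_distribution)
  sides <- ceiling(sqrt(seq_along(p)))
  ea <- sum(outer(p, p) * outer(sides, sides, function(a, b) (a + b + 1)^2))
  loss <- 1 - exp(-dose_rate * ea)
  new_loss_estimate(dose_rate, "analytic_size_dist", loss, 0, NA, NA,
                    NA, NULL, 8L, NULL)
}

#' Count electrons into an image
#'
#' Thresholds, labels and localizes every frame's puddles, accumulating
#' one count per puddle at its localization pixel (the L4 image). With
#' `common_mode = TRUE` and/or an area filter this implements
#' fine-calibration counting.
#'
#' @param stack a [frame_stack()].
#' @param calib a [calibration_frame()].
#' @param strategy localization strategy (see [localize_puddle()]).
#' @param connectivity 8 or 4.
#' @param common_mode apply [common_mode_correct()] per frame first.
#' @param block_shape common-mode block shape.
#' @param min_area,max_area puddle area filter (fine calibration).
#' @return list with `counted` (integer image), `events_per_frame`, and
#'   `counted_dose` (events per pixel per frame).
#' @export
count_frames <- function(stack, calib,
                         strategy = c("unweighted_centroid",
                                      "weighted_centroid", "max_pixel"),
                         connectivity = 8L, common_mode = FALSE,
                         block_shape = c(4L, 256L), min_area = 1L,
                         max_area = Inf) {
  strategy <- match.arg(strategy)
  d <- frame_dims(stack)
  if (!identical(d, dim(calib$threshold)))
    stop("stack and calibration shapes do not match")
  counted <- matrix(0L, d[1], d[2])
  nf <- n_frames(stack)
  events <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(stack, i)
    if (common_mode) fr <- common_mode_correct(fr, calib, block_shape)
    mask <- threshold_frame(fr, calib)
    if (!any(mask)) next
    ps <- label_components(mask, fr, connectivity)
    if (min_area > 1L || is.finite(max_area))
      ps <- area_filter(ps, max_area = max_area, min_area = min_area)
    if (ps$n == 0L) next
    loc <- localize_puddle(ps, strategy = strategy)
    counted <- add_at(counted, loc[, 1] + (loc[, 2] - 1L) * d[1],
                      rep.int(1L, nrow(loc)))
    events[i] <- ps$n
  }
  storage.mode(counted) <- "integer"
  list(counted = counted, events_per_frame = events,
       counted_dose = sum(events) / (prod(d) * nf))
}

#' Puddle size and shape statistics
#'
#' Size histogram and per-size shape-motif frequencies (motifs are fixed
#' polyplets, canonicalized by translation only) of the puddles in a set
#' of binary maps or L1-L3 reduced frames. L4 data is rejected: counted
#' frames retain no shape information.
#'
#' @param x a logical mask, a list of masks, or a list of `reduced_frame`s
#'   at level 1-3.
#' @param connectivity 8 or 4.
#' @return list with `size_histogram` (named counts by area), `motifs`
#'   (per size, a sorted table of motif keys "dr,dc;..." with counts) and
#'   `n_puddles`.
#' @export
puddle_statistics <- function(x, connectivity = 8L) {
  if (is.matrix(x)) x <- list(x)
  masks <- lapply(x, function(el) {
    if (inherits(el, "reduced_frame")) {
      if (el$level == 4L)
        stop("L4 (counted) data carries no shape information")
      ex <- expand_frame(el)
      if (el$level == 1L) ex > 0 else if (el$level == 2L) ex$mask else ex
    } else el
  })
  sizes <- integer(0)
  keys <- character(0)
  for (m in masks) {
    if (!any(m)) next
    ps <- label_components(m, connectivity = connectivity)
    sizes <- c(sizes, ps$area)
    keys <- c(keys, vapply(ps$pixels, shape_key, character(1)))
  }
  motifs <- lapply(split(keys, sizes), function(k) sort(table(k), decreasing = TRUE))
  list(size_histogram = table(sizes), motifs = motifs,
       n_puddles = length(sizes))
}

#' Benchmark reducibility and compressibility across dose rates
#'
#' For each dose rate, simulates a movie, reduces it at each requested
#' level and compresses the payloads with each codec, recording the
#' reduction-only ratio (raw bytes / reduced payload bytes) and the
#' reduction-compression ratio (raw bytes / compressed payload bytes).
#' Level 0 rows benchmark compression of the unreduced raw frames.
#'
#' @param doses dose rates (e/pixel/frame).
#' @param levels reduction levels (subset of 0:4; 0 = unreduced).
#' @param codecs a [codec_spec()] or list of them.
#' @param dims,n_frames,shapes,seed simulation settings (passed to
#'   [simulation_config()]).
#' @param sigma calibration threshold sigma.
#' @return data frame of `BenchmarkRecord`s: dose_rate, level, codec,
#'   optimization, prefilter, bytes_raw, bytes_reduced, bytes_compressed,
#'   reduction_ratio, reduction_compression_ratio.
#' @export
benchmark_reduction_compression <- function(doses, levels = c(0:4),
                                            codecs = default_codec(),
                                            dims = c(256L, 256L),
                                            n_frames = 10L,
                                            shapes = shape_library("parametric"),
                                            seed = 1L, sigma = 4) {
  if (inherits(codecs, "codec_spec")) codecs <- list(codecs)
  rows <- list()
  for (dose in doses) {
    cfg <- simulation_config(dose, dims = dims, n_frames = n_frames,
                             shapes = shapes, seed = seed)
    sim <- simulate_frames(cfg)
    calib <- sim_calibration(cfg, sigma = sigma)
    bytes_px <- ceiling(cfg$bit_depth / 8)
    bytes_raw <- as.double(n_frames) * prod(dims) * bytes_px
    raw_payloads <- lapply(seq_len(n_frames), function(i)
      frame_to_bytes(get_frame(sim$stack, i), cfg$bit_depth))
    for (lvl in levels) {
      payloads <- if (lvl == 0L) raw_payloads else {
        lapply(seq_len(n_frames), function(i) {
          rf <- reduce_frame(get_frame(sim$stack, i), calib, lvl,
                             bit_depth = cfg$bit_depth)
          c(list(rf$binary_payload),
            if (!is.null(rf$intensity_payload)) list(rf$intensity_payload))
        })
      }
      flat <- if (lvl == 0L) payloads else unlist(payloads, recursive = FALSE)
      bytes_reduced <- sum(vapply(flat, length, 0))
      for (cd in codecs) {
        bytes_compressed <- sum(vapply(flat, function(p)
          length(compress_block(p, cd)), 0))
        rows[[length(rows) + 1L]] <- data.frame(
          dose_rate = dose, level = lvl,
          codec = cd$algorithm, optimization = cd$optimization,
          prefilter = cd$prefilter,
          bytes_raw = bytes_raw, bytes_reduced = bytes_reduced,
          bytes_compressed = bytes_compressed,
          reduction_ratio = bytes_raw / bytes_reduced,
          reduction_compression_ratio = bytes_raw / bytes_compressed)
      }
    }
  }
  do.call(rbind, rows)
}

# nearest-neighbour distance histogram over per-frame point sets;
# breaks are 0:n_bins pixels, distances beyond n_bins are dropped
nn_histogram <- function(frame, row, col, n_bins = 30L) {
  counts <- numeric(n_bins)
  for (sel in split(seq_along(frame), frame)) {
    k <- length(sel)
    if (k < 2L) next
    dr <- outer(row[sel], row[sel], "-")
    dc <- outer(col[sel], col[sel], "-")
    dist <- sqrt(dr^2 + dc^2)
    diag(dist) <- Inf
    nn <- apply(dist, 1, min)
    b <- findInterval(nn[nn < n_bins], seq_len(n_bins))  # bin i: [i-1, i)
    tb <- tabulate(b + 1L, nbins = n_bins)
    counts <- counts + tb
  }
  counts
}

#' Estimate the primary-to-backscatter ratio from counted events
#'
#' Backscattered electrons re-enter the sensor near their primary and
#' create an excess of small nearest-neighbour puddle distances in
#' ultra-sparse data. The estimator compares the observed per-frame
#' nearest-neighbour distance histogram with histograms simulated at the
#' same event rate for a grid of candidate backscatter spawn fractions
#' (common random numbers across candidates), picking the fraction with
#' the least-squares best match over the small-distance bins.
#'
#' @param events data frame with `frame`, `row`, `col` of counted events
#'   (e.g. L4 localizations), at least 1000 of them.
#' @param dims frame shape the events live on.
#' @param n_frames number of frames the events came from.
#' @param displacement_sd assumed per-axis backscatter displacement scale
#'   (pixels), matching [inject_backscatter()].
#' @param candidates candidate spawn fractions to simulate.
#' @param n_bins,fit_bins histogram bins (1-pixel wide) and the bins used
#'   in the fit (small distances, where the backscatter excess lives).
#' @param seed RNG seed for the comparison simulations.
#' @return list with `spawn_fraction` (backscatter events per primary),
#'   `ratio` (primary:backscatter, `Inf` if no backscatter detected),
#'   `event_fraction`, and the fit curve (`candidates`, `sse`).
#' @export
estimate_backscatter_ratio <- function(events, dims, n_frames,
                                       displacement_sd = 5,
                                       candidates = seq(0, 0.3, by = 0.05),
                                       n_bins = 30L, fit_bins = 1:15,
                                       seed = 7L) {
  n_ev <- nrow(events)
  if (n_ev < 1000L)
    stop("too few events (", n_ev, " < 1000) for a powered backscatter estimate")
  obs <- nn_histogram(events$frame, events$row, events$col, n_bins) / n_ev
  rate <- n_ev / (as.double(prod(dims)) * n_frames)
  sim_hist <- function(p) {
    # same seed for every candidate: common random numbers
    with_seed(seed, {
      lp <- rate / (1 + p)
      k <- rpois(n_frames, lp * prod(dims))
      n <- sum(k)
      fr <- rep.int(seq_len(n_frames), k)
      r <- sample.int(dims[1], n, replace = TRUE)
      c <- sample.int(dims[2], n, replace = TRUE)
      spawn <- runif(n) < p
      nb <- sum(spawn)
      if (nb > 0L) {
        br <- ((r[spawn] + round(rnorm(nb, 0, displacement_sd)) - 1L) %% dims[1]) + 1L
        bc <- ((c[spawn] + round(rnorm(nb, 0, displacement_sd)) - 1L) %% dims[2]) + 1L
        fr <- c(fr, fr[spawn]); r <- c(r, br); c <- c(c, bc)
      }
      nn_histogram(fr, r, c, n_bins) / length(fr)
    })
  }
  hists <- lapply(candidates, sim_hist)
  sse <- vapply(hists, function(h) sum((h[fit_bins] - obs[fit_bins])^2), 0)
  # refine by linear interpolation of histograms between grid points
  p_fine <- seq(min(candidates), max(candidates), by = 0.002)
  sse_fine <- vapply(p_fine, function(p) {
    hi <- findInterval(p, candidates, all.inside = TRUE)
    w <- (p - candidates[hi]) / (candidates[hi + 1] - candidates[hi])
    h <- (1 - w) * hists[[hi]][fit_bins] + w * hists[[hi + 1]][fit_bins]
    sum((h - obs[fit_bins])^2)
  }, 0)
  p_hat <- p_fine[which.min(sse_fine)]
  list(spawn_fraction = p_hat,
       ratio = if (p_hat < 0.005) Inf else 1 / p_hat,
       event_fraction = p_hat / (1 + p_hat),
       detectable = p_hat >= 0.005,
       candidates = candidates, sse = sse)
}

#' Estimate the false-positive floor from a dose series
#'
#' In a dilution series where the true dose shrinks geometrically
#' (`d0 * g^k`) while the detector's false-positive rate stays constant,
#' the counted dose rates follow `counted_k = d0 * g^k + f`. Least squares
#' (linear in `d0` and `f` for known `g`) recovers the floor `f` and the
#' initial true dose `d0`.
#'
#' @param counted_rates counted dose rates per step (e/pixel/frame),
#'   highest dose first; at least 3 steps.
#' @param dilution true-dose reduction factor per step.
#' @return list with `floor` (f), `d0`, `fitted` rates and `residuals`.
#' @export
estimate_false_positive_rate <- function(counted_rates, dilution) {
  n <- length(counted_rates)
  if (n < 3L) stop("need at least 3 dose steps")
  g <- (1 / dilution)^(seq_len(n) - 1)
  incr <- diff(counted_rates) > 0
  if (any(incr & diff(counted_rates) > 0.05 * counted_rates[-n]))
    warning("counted rates are non-monotone beyond noise")
  X <- cbind(g = g, one = 1)
  fit <- stats::lm.fit(X, counted_rates)
  f <- max(0, unname(fit$coefficients["one"]))
  d0 <- unname(fit$coefficients["g"])
  list(floor = f, d0 = d0, fitted = as.vector(X %*% fit$coefficients),
       residuals = as.vector(fit$residuals))
}
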