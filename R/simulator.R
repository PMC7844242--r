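#' Electron puddle shape library
#'
#' The set of puddle footprints an incident electron can stamp, with
#' sampling probabilities and per-pixel ADU weight patterns. Offsets are
#' relative to the anchor pixel (the electron's entry point), which is the
#' first pixel of the shape in row-major order and always carries weight 1;
#' remaining pixels model charge sharing with weights between 0.5 and 1.
#'
#' Fixed modes stamp every pixel at full amplitude (idealized square point
#' spread functions). The parametric mode mimics a back-thinned detector in
#' counting conditions: puddle sizes follow a truncated geometric law with
#' ~80% of puddles below three pixels, and for each size every fixed
#' (translation-distinct, 8-connected) polyplet of that size is equally
#' likely.
#'
#' @param mode `"fixed_1px"`, `"fixed_2x2"`, `"fixed_3x3"` or
#'   `"parametric"`.
#' @param max_size largest parametric puddle size (pixels, <= 6; default 5).
#' @param geom_p geometric size parameter; the default `1 - sqrt(0.2)`
#'   puts 80% of mass on sizes 1-2.
#' @param seed RNG seed for the charge-sharing weight patterns.
#' @return an object of class `shape_library`: list with `offsets` (list of
#'   2-column dr/dc matrices), `weights`, `prob`, `size`, `mode`.
#' @export
shape_library <- function(mode = c("parametric", "fixed_1px", "fixed_2x2",
                                   "fixed_3x3"),
                          max_size = 5L, geom_p = 1 - sqrt(0.2), seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "parametric") {
    offs <- switch(mode,
      fixed_1px = matrix(0L, 1, 2),
      fixed_2x2 = as.matrix(expand.grid(0:1, 0:1))[, 2:1],
      fixed_3x3 = as.matrix(expand.grid(0:2, 0:2))[, 2:1])
    offs <- offs[order(offs[, 1], offs[, 2]), , drop = FALSE]
    dimnames(offs) <- list(NULL, c("dr", "dc"))
    lib <- list(offsets = list(offs), weights = list(rep(1, nrow(offs))),
                prob = 1, size = nrow(offs), mode = mode)
    return(structure(lib, class = "shape_library"))
  }
  if (max_size > 6L) stop("parametric libraries support sizes up to 6")
  size_probs <- geom_p * (1 - geom_p)^(seq_len(max_size) - 1)
  size_probs <- size_probs / sum(size_probs)
  offsets <- list(); prob <- numeric(0); size <- integer(0)
  for (s in seq_len(max_size)) {
    shapes <- enumerate_fixed_polyplets(s)$shapes
    offsets <- c(offsets, lapply(shapes, anchor_offsets))
    prob <- c(prob, rep(size_probs[s] / length(shapes), length(shapes)))
    size <- c(size, rep(s, length(shapes)))
  }
  weights <- with_seed(seed, lapply(offsets, function(o) {
    w <- runif(nrow(o), 0.5, 1)
    w[1] <- 1
    w
  }))
  structure(list(offsets = offsets, weights = weights, prob = prob,
                 size = size, mode = mode),
            class = "shape_library")
}

# translate a shape so its first row-major pixel sits at (0, 0)
anchor_offsets <- function(off) {
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  off <- sweep(off, 2, off[1, ])
  dimnames(off) <- list(NULL, c("dr", "dc"))
  storage.mode(off) <- "integer"
  off
}

#' @export
print.shape_library <- function(x, ...) {
  cat(sprintf("<shape_library> %s: %d shape(s), sizes %s\n",
              x$mode, length(x$offsets),
              paste(range(x$size), collapse = "-")))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic electron-event generator: Poisson electron
#' arrivals at `dose_rate` e/pixel/frame, puddle footprints drawn from a
#' [shape_library()], right-skewed (lognormal) single-hit amplitudes,
#' per-pixel Gaussian dark noise and gain, optional backscatter spawning
#' and a constant false-positive event rate.
#'
#' @param dose_rate electron flux, e/pixel/frame (>= 0).
#' @param dims frame `c(height, width)`.
#' @param n_frames frames to generate.
#' @param shapes a [shape_library()].
#' @param amplitude_mean mean single-electron amplitude (ADU above dark);
#'   the default (10 x the default dark sd of 4 ADU) keeps every stamped
#'   pixel comfortably supra-threshold at a 3-4 sigma calibration.
#' @param amplitude_sdlog lognormal shape parameter (0 = constant
#'   amplitude).
#' @param dark_mean,dark_sd per-pixel dark model; scalars or `H x W`
#'   matrices.
#' @param gain per-pixel gain (scalar or matrix, ADU multiplier on
#'   deposited signal).
#' @param bit_depth digitizer bits (values are clamped to `2^bit_depth-1`).
#' @param boundary `"periodic"` (events wrap; conserves stamped intensity,
#'   preferred for coincidence studies) or `"clip"` (pixels falling off the
#'   frame are lost, imaging-like).
#' @param backscatter `NULL`, or `list(fraction =, displacement_sd =)`:
#'   each primary independently spawns a backscatter event with the given
#'   probability, displaced by a round(Normal(0, sd)) offset per axis.
#' @param fp_rate constant false-positive event rate (single-pixel events,
#'   e/pixel/frame) superimposed on the true dose.
#' @param seed RNG seed fixing the full output.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(dose_rate, dims = c(256L, 256L), n_frames = 10L,
                              shapes = shape_library("parametric"),
                              amplitude_mean = 40, amplitude_sdlog = 0.25,
                              dark_mean = 100, dark_sd = 4, gain = 1,
                              bit_depth = 16L,
                              boundary = c("periodic", "clip"),
                              backscatter = NULL, fp_rate = 0,
                              seed = NULL) {
  boundary <- match.arg(boundary)
  if (dose_rate < 0) stop("`dose_rate` must be >= 0")
  if (!is.null(backscatter)) {
    stopifnot(backscatter$fraction >= 0, backscatter$fraction < 1)
    backscatter$displacement_sd <- backscatter$displacement_sd %||% 5
  }
  structure(list(dose_rate = dose_rate, dims = as.integer(dims),
                 n_frames = as.integer(n_frames), shapes = shapes,
                 amplitude_mean = amplitude_mean,
                 amplitude_sdlog = amplitude_sdlog,
                 dark_mean = dark_mean, dark_sd = dark_sd, gain = gain,
                 bit_depth = as.integer(bit_depth), boundary = boundary,
                 backscatter = backscatter, fp_rate = fp_rate, seed = seed),
            class = "simulation_config")
}

# draw primary (and false-positive) event anchors for all frames
draw_events <- function(cfg) {
  npx <- prod(cfg$dims)
  k <- rpois(cfg$n_frames, cfg$dose_rate * npx)
  n <- sum(k)
  ev <- data.frame(
    frame = rep.int(seq_len(cfg$n_frames), k),
    row = sample.int(cfg$dims[1], n, replace = TRUE),
    col = sample.int(cfg$dims[2], n, replace = TRUE),
    shape = sample.int(length(cfg$shapes$offsets), n, replace = TRUE,
                       prob = cfg$shapes$prob),
    type = rep("primary", n),
    stringsAsFactors = FALSE)
  if (cfg$fp_rate > 0) {
    kf <- rpois(cfg$n_frames, cfg$fp_rate * npx)
    nf <- sum(kf)
    one_px <- which(vapply(cfg$shapes$offsets, nrow, 0L) == 1L)[1]
    if (is.na(one_px)) stop("false positives need a 1-pixel shape in the library")
    fp <- data.frame(
      frame = rep.int(seq_len(cfg$n_frames), kf),
      row = sample.int(cfg$dims[1], nf, replace = TRUE),
      col = sample.int(cfg$dims[2], nf, replace = TRUE),
      shape = rep(one_px, nf), type = rep("false_positive", nf),
      stringsAsFactors = FALSE)
    ev <- rbind(ev, fp)
    ev <- ev[order(ev$frame), ]
  }
  ev
}

#' Spawn backscatter events from primaries
#'
#' Each primary event independently spawns one backscattered event with
#' probability `fraction`, displaced from its parent by a rounded
#' Normal(0, `displacement_sd`) offset per axis (periodic wrap or clip to
#' the frame). A zero displacement lands the backscatter on its parent,
#' where it merges into the parent puddle (coincidence).
#'
#' @param events event table as from [simulate_frames()] (`frame`, `row`,
#'   `col`, `shape`, `type` columns).
#' @param fraction spawn probability in `[0, 1)`.
#' @param displacement_sd per-axis displacement scale (pixels).
#' @param dims frame dimensions.
#' @param boundary `"periodic"` or `"clip"`.
#' @param shapes optional [shape_library()] to redraw footprints for the
#'   spawned events (default: inherit the parent's shape).
#' @param seed optional RNG seed.
#' @return the augmented event table (spawned rows have
#'   `type = "backscatter"`).
#' @export
inject_backscatter <- function(events, fraction, displacement_sd = 5,
                               dims, boundary = "periodic", shapes = NULL,
                               seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  if (fraction == 0 || nrow(events) == 0L) return(events)
  with_seed(seed, {
    prim <- events[events$type == "primary", , drop = FALSE]
    spawn <- runif(nrow(prim)) < fraction
    bs <- prim[spawn, , drop = FALSE]
    if (nrow(bs) > 0L) {
      dr <- round(rnorm(nrow(bs), 0, displacement_sd))
      dc <- round(rnorm(nrow(bs), 0, displacement_sd))
      r <- bs$row + dr
      c <- bs$col + dc
      if (boundary == "periodic") {
        r <- ((r - 1L) %% dims[1]) + 1L
        c <- ((c - 1L) %% dims[2]) + 1L
      } else {
        keep <- r >= 1L & r <= dims[1] & c >= 1L & c <= dims[2]
        bs <- bs[keep, , drop = FALSE]
        r <- r[keep]; c <- c[keep]
      }
      bs$row <- as.integer(r); bs$col <- as.integer(c)
      if (!is.null(shapes))
        bs$shape <- sample.int(length(shapes$offsets), nrow(bs),
                               replace = TRUE, prob = shapes$prob)
      bs$type <- "backscatter"
      events <- rbind(events, bs)
      events <- events[order(events$frame), ]
    }
    events
  })
}

# stamp one frame's events onto a numeric signal matrix (ADU) or, with
# amplitudes NULL, onto a logical mask
stamp_events <- function(rows, cols, shape_ids, shapes, dims, boundary,
                         amplitudes = NULL) {
  npx <- prod(dims)
  signal <- if (is.null(amplitudes)) logical(npx) else numeric(npx)
  for (s in unique(shape_ids)) {
    sel <- shape_ids == s
    off <- shapes$offsets[[s]]
    m <- nrow(off)
    ks <- sum(sel)
    rr <- rep(rows[sel], each = m) + rep.int(off[, 1], ks)
    cc <- rep(cols[sel], each = m) + rep.int(off[, 2], ks)
    if (boundary == "periodic") {
      rr <- ((rr - 1L) %% dims[1]) + 1L
      cc <- ((cc - 1L) %% dims[2]) + 1L
      keep <- rep.int(TRUE, length(rr))
    } else {
      keep <- rr >= 1L & rr <= dims[1] & cc >= 1L & cc <= dims[2]
    }
    idx <- rr[keep] + (cc[keep] - 1L) * dims[1]
    if (is.null(amplitudes)) {
      signal[idx] <- TRUE
    } else {
      val <- (rep(amplitudes[sel], each = m) *
                rep.int(shapes$weights[[s]], ks))[keep]
      signal <- add_at(signal, idx, val)
    }
  }
  matrix(signal, dims[1], dims[2])
}

#' Simulate a movie of electron events
#'
#' Generates `n_frames` frames of Poisson electron arrivals: each frame
#' draws `Poisson(dose_rate * H * W)` electrons at uniform positions, each
#' stamping its footprint's ADU pattern (additively where puddles
#' overlap), then per-pixel gain, Gaussian dark noise and quantization are
#' applied. The ground-truth event list is returned for recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @return list with `stack` (a [frame_stack()]) and `events` (data frame:
#'   `frame`, `row`, `col` anchor, `shape`, `amplitude`, `type`).
#' @export
simulate_frames <- function(cfg) {
  with_seed(cfg$seed, {
    d <- cfg$dims
    npx <- prod(d)
    ev <- draw_events(cfg)
    if (!is.null(cfg$backscatter))
      ev <- inject_backscatter(ev, cfg$backscatter$fraction,
                               cfg$backscatter$displacement_sd,
                               dims = d, boundary = cfg$boundary,
                               shapes = cfg$shapes)
    ev$amplitude <- if (cfg$amplitude_sdlog > 0)
      rlnorm(nrow(ev), log(cfg$amplitude_mean) - cfg$amplitude_sdlog^2 / 2,
             cfg$amplitude_sdlog)
    else rep(cfg$amplitude_mean, nrow(ev))
    gain <- if (is.matrix(cfg$gain)) cfg$gain else matrix(cfg$gain, d[1], d[2])
    dark <- if (is.matrix(cfg$dark_mean)) cfg$dark_mean
            else matrix(cfg$dark_mean, d[1], d[2])
    dsd <- if (is.matrix(cfg$dark_sd)) cfg$dark_sd
           else matrix(cfg$dark_sd, d[1], d[2])
    lim <- 2^cfg$bit_depth - 1
    frames <- array(0L, c(d[1], d[2], cfg$n_frames))
    split_idx <- split(seq_len(nrow(ev)), factor(ev$frame, levels = seq_len(cfg$n_frames)))
    for (i in seq_len(cfg$n_frames)) {
      sel <- split_idx[[i]]
      signal <- if (length(sel) == 0L) 0
        else stamp_events(ev$row[sel], ev$col[sel], ev$shape[sel],
                          cfg$shapes, d, cfg$boundary,
                          amplitudes = ev$amplitude[sel]) * gain
      fr <- round(dark + rnorm(npx, 0, dsd) + signal)
      frames[, , i] <- pmin(pmax(fr, 0), lim)
    }
    list(stack = frame_stack(frames, bit_depth = cfg$bit_depth,
                             source = "simulated"),
         events = ev)
  })
}

#' Reference calibration for a simulation
#'
#' The thresholds a perfectly calibrated detector would use for a
#' simulation's dark model: `dark_mean + qnorm(1 - r) * dark_sd` per
#' pixel.
#'
#' @param cfg a [simulation_config()].
#' @param sigma one-sided sigma multiple (overrides `r`).
#' @param r false-positive rate.
#' @return a [calibration_frame()].
#' @export
sim_calibration <- function(cfg, sigma = NULL, r = pnorm(-3)) {
  if (!is.null(sigma)) r <- pnorm(-sigma)
  d <- cfg$dims
  dark <- if (is.matrix(cfg$dark_mean)) cfg$dark_mean
          else matrix(cfg$dark_mean, d[1], d[2])
  dsd <- if (is.matrix(cfg$dark_sd)) cfg$dark_sd
         else matrix(cfg$dark_sd, d[1], d[2])
  gain <- if (is.matrix(cfg$gain)) cfg$gain else matrix(cfg$gain, d[1], d[2])
  calibration_frame(dark + qnorm(1 - r) * dsd, dark = dark, gain = gain, r = r)
}

#' Simulate a dose series with a false-positive floor
#'
#' Emulates the controlled dose-rate dilution used to measure
#' false-positive rates: successive acquisitions reduce the true dose by a
#' fixed factor (e.g. raising magnification at constant flux) while any
#' detector false-positive rate stays constant, so counted dose rates decay
#' geometrically onto the false-positive floor.
#'
#' @param base_cfg a [simulation_config()] for the first (highest-dose)
#'   step.
#' @param n_steps number of acquisitions (>= 2).
#' @param dilution true-dose reduction factor per step (default 200).
#' @param fp_rate constant false-positive event rate (e/pixel/frame).
#' @return list of per-step lists `(stack, events, true_dose)`.
#' @export
simulate_dose_series <- function(base_cfg, n_steps, dilution = 200,
                                 fp_rate = 0) {
  if (n_steps < 2L) stop("need at least 2 dose steps")
  lapply(seq_len(n_steps), function(k) {
    cfg <- base_cfg
    cfg$dose_rate <- base_cfg$dose_rate / dilution^(k - 1)
    cfg$fp_rate <- fp_rate
    cfg$seed <- if (is.null(base_cfg$seed)) NULL else base_cfg$seed + k
    sim <- simulate_frames(cfg)
    list(stack = sim$stack, events = sim$events, true_dose = cfg$dose_rate)
  })
}
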