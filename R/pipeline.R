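#' Pipeline configuration
#'
#' Settings for the chunked, multi-worker reduce-compress-write pipeline.
#' Frames are processed in contiguous chunks round-robined over workers;
#' each worker appends to its own part file and the parts are merged into
#' one time-ordered container at the end. The output content is a pure
#' function of the source frames, the calibration timeline and the
#' reduction/codec settings: worker count and chunking never change it.
#'
#' @param level reduction level 1..4.
#' @param codec a [codec_spec()].
#' @param statistic L2 summary statistic.
#' @param strategy L4 localization strategy.
#' @param n_workers parallel workers (part files), >= 1.
#' @param chunk_frames frames per work unit (default 16).
#' @param raw_retention_interval keep every k-th raw frame (`NULL` = none).
#' @param calibration_path threshold TIFF to (re)load, if the calibration
#'   comes from disk.
#' @param calibration_reload_interval reload the threshold frame every k
#'   chunks (`NULL` = load once).
#' @param connectivity puddle connectivity.
#' @param bit_depth packed ADU bits (default: the source bit depth).
#' @param timestamp_period timestamp increment per frame.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(level = 1L, codec = default_codec(),
                            statistic = "max", strategy = "unweighted_centroid",
                            n_workers = 1L, chunk_frames = 16L,
                            raw_retention_interval = NULL,
                            calibration_path = NULL,
                            calibration_reload_interval = NULL,
                            connectivity = 8L, bit_depth = NULL,
                            timestamp_period = 1) {
  if (n_workers < 1L) stop("`n_workers` must be >= 1")
  if (chunk_frames < 1L) stop("`chunk_frames` must be >= 1")
  structure(list(level = as.integer(level), codec = codec,
                 statistic = statistic, strategy = strategy,
                 n_workers = as.integer(n_workers),
                 chunk_frames = as.integer(chunk_frames),
                 raw_retention_interval = raw_retention_interval,
                 calibration_path = calibration_path,
                 calibration_reload_interval = calibration_reload_interval,
                 connectivity = as.integer(connectivity),
                 bit_depth = bit_depth,
                 timestamp_period = timestamp_period),
            class = "pipeline_config")
}

# calibration for a given (1-based) global chunk index: a provider function
# overrides; otherwise the calibration file is (re)read at reload
# boundaries, falling back to the previous thresholds on failure
chunk_calibration <- function(cfg, chunk_idx, provider, fallback) {
  if (!is.null(provider)) return(provider(chunk_idx))
  if (is.null(cfg$calibration_path)) return(fallback)
  interval <- cfg$calibration_reload_interval
  if (!is.null(fallback) && (is.null(interval) ||
                             (chunk_idx - 1L) %% interval != 0L))
    return(fallback)
  new <- tryCatch(read_calibration_tiff(cfg$calibration_path),
                  error = function(e) NULL)
  if (is.null(new)) {
    warning("could not reload thresholds at chunk ", chunk_idx,
            "; keeping previous calibration")
    return(fallback)
  }
  new
}

#' Run the reduce-compress-write pipeline
#'
#' Calibrate, threshold, reduce, compress and write a frame stack over
#' chunked frame streams with `n_workers` workers. Each worker writes an
#' intermediate part file; the parts are merged into a single
#' time-ordered, indexed container. A worker failure aborts the pipeline
#' and preserves the part files for diagnosis.
#'
#' @param source a [frame_stack()].
#' @param cfg a [pipeline_config()].
#' @param out_path output container path.
#' @param calib a [calibration_frame()] (or `NULL` to load from
#'   `cfg$calibration_path`).
#' @param calibration_provider optional `function(chunk_idx)` returning the
#'   [calibration_frame()] to use for that chunk; models on-the-fly
#'   threshold reloads deterministically.
#' @return list with `container` (a `recode_container`) and `report`
#'   (frames, signal pixels, puddles, bytes in/out, ratio).
#' @export
run_pipeline <- function(source, cfg = pipeline_config(), out_path,
                         calib = NULL, calibration_provider = NULL) {
  nf <- n_frames(source)
  bd <- cfg$bit_depth %||% source$bit_depth
  if (is.null(calib) && is.null(calibration_provider)) {
    if (is.null(cfg$calibration_path))
      stop("no calibration: pass `calib`, `calibration_provider` or set cfg$calibration_path")
    calib <- read_calibration_tiff(cfg$calibration_path)
  }
  chunk_starts <- seq.int(1L, nf, by = cfg$chunk_frames)
  chunks <- lapply(seq_along(chunk_starts), function(j) {
    list(idx = j,
         frames = chunk_starts[j]:min(chunk_starts[j] + cfg$chunk_frames - 1L, nf),
         worker = (j - 1L) %% cfg$n_workers + 1L)
  })
  part_paths <- sprintf("%s.part%03d", out_path, seq_len(cfg$n_workers))

  process_worker <- function(w) {
    mine <- Filter(function(ch) ch$worker == w, chunks)
    if (length(mine) == 0L) return(NULL)
    current <- calib
    frames <- list()
    numbers <- integer(0)
    for (ch in mine) {
      current <- chunk_calibration(cfg, ch$idx, calibration_provider, current)
      if (!inherits(current, "calibration_frame") && !is.matrix(current))
        stop("no usable calibration for chunk ", ch$idx)
      if (!identical(frame_dims(source),
                     dim(if (is.matrix(current)) current else current$threshold)))
        stop("calibration shape does not match source frames")
      for (i in ch$frames) {
        frames[[length(frames) + 1L]] <-
          reduce_frame(get_frame(source, i), current, cfg$level,
                       statistic = cfg$statistic, strategy = cfg$strategy,
                       bit_depth = bd, connectivity = cfg$connectivity)
        numbers <- c(numbers, i)
      }
    }
    write_reduced(frames, part_paths[w], codec = cfg$codec,
                  frame_numbers = numbers,
                  timestamps = (numbers - 1) * cfg$timestamp_period,
                  raw_retention_interval = cfg$raw_retention_interval,
                  source_stack = source, frame_rate = source$frame_rate,
                  finalize = FALSE)
    part_paths[w]
  }

  results <- if (cfg$n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(cfg$n_workers), process_worker,
                       mc.cores = cfg$n_workers)
  } else {
    lapply(seq_len(cfg$n_workers), process_worker)
  }
  errs <- Filter(function(r) inherits(r, "try-error") || inherits(r, "condition"),
                 results)
  if (length(errs))
    stop("pipeline worker failed (part files preserved): ",
         conditionMessage(errs[[1]]))
  used <- unlist(Filter(Negate(is.null), results))
  container <- merge_parts(used, out_path)
  file.remove(used)
  idx <- container$index
  bytes_in <- as.double(nf) * prod(frame_dims(source)) * ceiling(bd / 8)
  report <- list(frames = nrow(idx),
                 signal_pixels = sum(idx$n_signal),
                 puddles = if (all(idx$n_puddles == 4294967295)) NA
                           else sum(idx$n_puddles[idx$n_puddles != 4294967295]),
                 bytes_in = bytes_in,
                 bytes_out = file.size(out_path),
                 ratio = bytes_in / file.size(out_path))
  list(container = container, report = report)
}
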