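# Independent oracles and small fixture builders used across the suite.

# flood-fill connected components, deliberately naive (queue-based BFS)
flood_fill_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  nbr <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || labels[r0, c0] != 0L) next
    lab <- lab + 1L
    queue <- list(c(r0, c0))
    labels[r0, c0] <- lab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- lab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  list(labels = labels, n = lab)
}

# partition signature invariant to label numbering
partition_key <- function(labels) {
  idx <- which(labels != 0L)
  unname(sort(vapply(split(idx, labels[idx]),
                     function(px) paste(sort(px), collapse = "-"),
                     character(1))))
}

# brute-force fixed polyplet enumeration: all size-n subsets of an n x n
# grid, connectivity-checked, deduplicated by translation
brute_polyplets <- function(size) {
  if (size == 1L) return(1L)
  cells <- as.matrix(expand.grid(r = seq_len(size), c = seq_len(size)))
  combos <- utils::combn(nrow(cells), size)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  for (j in seq_len(ncol(combos))) {
    pix <- cells[combos[, j], , drop = FALSE]
    m <- matrix(FALSE, size, size)
    m[pix] <- TRUE
    if (flood_fill_components(m, 8L)$n != 1L) next
    key <- {
      p <- pix
      p[, 1] <- p[, 1] - min(p[, 1]); p[, 2] <- p[, 2] - min(p[, 2])
      p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
      paste(p[, 1], p[, 2], sep = ",", collapse = ";")
    }
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      count <- count + 1L
    }
  }
  count
}

rand_mask <- function(h, w, p) matrix(runif(h * w) < p, h, w)

# a tiny frame + calibration pair with known supra-threshold pixels
toy_frame <- function(h = 12L, w = 12L, thr = 100, seed = 1L) {
  set.seed(seed)
  frame <- matrix(sample(0:4095, h * w, replace = TRUE), h, w)
  list(frame = frame, calib = calibration_frame(matrix(thr, h, w)))
}
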