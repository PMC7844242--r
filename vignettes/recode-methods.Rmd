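---
title: "Reducing and compressing electron-counting detector movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing and compressing electron-counting detector movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recode)
```

## The problem

Direct electron detectors in movie mode digitize hundreds to thousands of
frames per second. In electron-counting conditions almost every pixel of
every frame holds only thermal/readout noise: the useful information is a
sparse scatter of *electron puddles* — small clusters of supra-threshold
pixels, each digitized from the secondary-charge cloud of one incident
electron. Storing the raw stream is prohibitively expensive and mostly
stores noise; integrating frames before storage destroys the temporal
resolution the detector was bought for. This package implements a data
reduction and compression scheme for such data: per-pixel signal/noise
calibration, four reduction levels that keep progressively less per-puddle
information, a lossless codec layer, an indexed container format written in
parallel and merged, a synthetic event generator, and the analysis methods
(coincidence loss, puddle statistics, backscatter and false-positive
estimation) that the retained information makes possible.

## Reduction levels

All levels start by thresholding each frame against a per-pixel ADU
threshold, giving a binary map of signal pixels. A pixel exactly at its
threshold is noise — the comparison is strictly greater-than — and dead
pixels carry an infinite threshold. The levels then keep:

* **L1** — the binary map plus the original ADU values of all signal
  pixels, bit-packed in row-major order. Lossless above threshold; data can
  be *recalibrated after acquisition* (different threshold, gain model, or
  counting strategy), which is why L1 stores raw rather than
  dark-subtracted ADUs.
* **L2** — the binary map plus one summary statistic (sum, max, or mean)
  per puddle, packed in label order. Serves diffraction-style applications
  that need dynamic range but not every pixel.
* **L3** — the binary map only. For `n`-bit input this is exactly a factor
  `n` reduction (`benchmark_reduction_compression()` reports 16 for 16-bit
  data) and is the cheapest level to compute.
* **L4** — one pixel per puddle, the estimated electron entry point: the
  counted image. Maximally compressible, but shape and intensity
  information is gone, so counting parameters must be fixed before
  acquisition.

Puddles are the connected components of the binary map, 8-connected by
default (diagonally touching pixels merge; 4-connectivity is selectable).
Components are labeled by a two-pass union-find pass in C; labels are
assigned in row-major first-touch order, which fixes the on-disk order of
L2 statistics. Localization offers the three standard strategies —
brightest pixel, intensity-weighted centroid, unweighted centroid —
with centroids rounded half-down per axis so that a uniform 2×2 puddle
maps deterministically to its top-left pixel. Any consistent tie-break
works at the resolutions involved; this one is fixed and tested.

The packed width of L2 statistics is the input bit depth for `max` and
`mean`; `sum` gets 8 extra bits of headroom (puddle areas are effectively
bounded well below 256 pixels on back-thinned detectors; larger sums clamp).

## Calibration

The fast ("on-the-fly") calibration takes a flat-field, low-dose stack and
derives per pixel:

* **dark level** — the pixel's median across frames (electrons are rare,
  so the median ignores them); a mean mode exists for speed at a slightly
  higher false-positive rate;
* **gain** — the median of the pixel's `N` largest dark-subtracted values,
  where `N` is the total dose per pixel in the calibration set, small
  enough that double hits are negligible. The calibration stack should
  deliver at least a few electrons per pixel, or the top-`N` values are
  noise-dominated;
* **dose** `N` — estimated from the data itself: in randomly placed 11×11
  patches (64 by default; the patch count and size are free choices),
  per-pixel thresholds are fitted from each pixel's own trace, components
  are labeled per frame, and a component is attributed to the patch centre
  when its maximum-value pixel sits there. The mean count over patches
  estimates `N`.

A single global threshold is the `(1 - r)` quantile of a normal fit to the
dark values, with `r` the tolerable false-positive rate per pixel per
frame. The default corresponds to a one-sided 3-sigma tail
(`r = pnorm(-3)`), with 4-sigma typical for stricter recalibration; both a
probability and a sigma-multiple are accepted. The normal fit uses sample
mean/SD — dark histograms are close to normal, and this matches the
method's assumptions — with a median/MAD robust mode as an option. The
global threshold is then adapted per pixel by shifting for the pixel's
dark level and scaling by its relative gain
(`build_calibration_frame()`); non-positive gains mark dead pixels.

The finer calibration adds two steps. Common-mode correction removes the
correlated thermal offset shared by a readout block (4×256 pixels on the
reference detector): the block's median dark-subtracted value over
*non-signal* pixels is subtracted. How signal pixels are masked during
this estimate is not prescribed anywhere; excluding pixels above their
threshold is this package's choice, and a block with no noise pixels
keeps offset 0 with a warning. Area filtering drops puddles outside an
area band to suppress false positives (and single-pixel puddles before
gain re-estimation). The fine path never counts more events than the fast
path on the same data, which the tests assert.

Thresholds are persisted as a single-page 32-bit float TIFF (values scaled
into libtiff's defined [0, 1] float range by 2^-17; the dead-pixel
sentinel is 1.0), and the pipeline can reload the threshold file at fixed
chunk intervals, so an external process can recalibrate during
acquisition. In code, the reload timeline is modeled by a deterministic
`calibration_provider(chunk_index)` function, keeping the output a pure
function of its inputs even under parallel workers.

## Codecs and container

Six lossless codecs (deflate, zstd, bzip2, lzma, lz4, snappy) are exposed
at each library's two extreme presets ("optimal speed" / "optimal
compression"; snappy has a single preset, to which both map). An optional
bitshuffle prefilter transposes bits within 64 KiB chunks — the chunk size
is fixed rather than tuned to a particular cache hierarchy, for
reproducibility. Binary-map and intensity payloads are compressed
*independently*, since their statistics differ, and every compressed block
carries a 12-byte self-describing header (codec registry id, preset,
prefilter, original length). Deflate at optimal speed is the reference
codec. Decompression failures and unknown codec ids raise errors; nothing
is silently repaired.

The container is a little-endian file with a fixed 512-byte header,
append-only per-frame records (frame number, timestamp, payload lengths,
CRC-32 per payload, flags), and an index footer appended at finalization
for O(1) random access. Worker part files are identical but footer-less
(indexed by scanning); merging interleaves records into strictly
increasing frame order, copying compressed bytes verbatim. Raw
(unreduced, uncompressed) source frames can be retained every k-th frame
for validation and post-hoc recalibration. The layout is this package's
own design — append-only during acquisition, O(1) access after merge —
and is not byte-compatible with any other tool. 64-bit fields are written
as two 32-bit words; offsets stay far below 2^53 so doubles represent
them exactly in memory.

The pipeline chunks the frame stream (16 frames per chunk by default),
round-robins chunks over workers, and merges the resulting parts. Workers
share nothing but the read-only source and write disjoint part files, so
the merged content is independent of the worker count and chunking — a
property the tests check by comparing 1-, 3-, 4- and 8-worker runs
frame by frame.

## The simulator

`simulate_frames()` generates the statistical structure the method
assumes, and returns the ground truth needed for recovery tests:

* electron arrivals per frame are Poisson with mean `dose_rate * H * W`,
  at uniform positions;
* each electron stamps a footprint from a `shape_library()`. Fixed 1×1,
  2×2 and 3×3 stamps support idealized point-spread-function studies; the
  parametric mode draws puddle sizes from a truncated geometric law with
  80% of mass on sizes 1–2 (matching how strongly back-thinned detectors
  concentrate on small puddles) and, within a size, uniformly over all
  fixed polyplets of that size (sizes up to 5 by default; the true
  per-detector shape spectrum is a configuration, not a constant, since
  it varies by detector and is not publicly tabulated);
* single-hit amplitudes are lognormal (right-skewed, as empirical
  single-electron spectra are) with mean 10× the default dark SD of 4
  ADU, so stamped pixels are comfortably supra-threshold at a 3–4 sigma
  calibration; the anchor pixel carries full amplitude and remaining
  pixels share charge with weights in [0.5, 1];
* per-pixel Gaussian dark noise (mean 100 ADU by default), per-pixel
  gain, quantization and bit-depth clamping follow;
* optional backscatter: each primary independently spawns a displaced
  secondary with some probability; optional constant false-positive event
  rate for dose-series studies.

The periodic boundary (default for coincidence studies) conserves stamped
intensity exactly and removes edge bias, so loss estimates depend only on
the dose rate and shapes, not the frame size; the clip boundary loses
intensity only at the edges and is used for imaging-like outputs.

What the simulator does *not* model: charge transport physics (amplitudes
and footprints are drawn independently), detector MTF/DQE, pixel
cross-talk, and temporally correlated dark drift (drift scenarios are
constructed explicitly in tests). Passing tests therefore demonstrate the
correctness of the reduction/compression machinery and the estimators
under the stated statistical model, not detector-physics fidelity.

## Coincidence loss

Two electrons whose puddles merge in one frame are counted once;
coincidence loss is defined here as `1 - components / incident electrons`
(electrons landing on one pixel or in one connected cluster merge). The
simulation estimator rasterizes noiseless binary stamps and labels
components with torus topology under the periodic boundary. At very low
expected events per frame the estimator switches to an exact sparse path:
two events merge if and only if their footprints overlap or touch, i.e.
their anchor displacement falls in a precomputed Minkowski set, so
union-find over the event adjacency graph yields the same component
counts without rasterizing — the per-frame equivalence of the two paths
is tested directly.

As the dose rate vanishes, loss/rate converges to half the pair-merge
neighbourhood size: 4.5 for 1-pixel stamps, 12.5 for 2×2, 24.5 for 3×3
under 8-connectivity (the displacement sets have 9, 25 and 49 elements,
including the same-anchor collision, and each merged pair loses one
event). The acceptance tests verify simulated convergence to these
constants and reproduce the reference coincidence-loss table at 1024×1024
over at least 100 frames per dose.

A deliberately coarse closed-form alternative
(`coincidence_loss_analytic()`) treats puddles as square bounding boxes of
their sampled size and thins the counted rate exponentially; it needs
only a size histogram, overestimates merging for non-square shapes
(tested to stay within a factor ~2 of simulation at low dose), and is
kept as a documented approximation rather than a reference value.

## Backscatter and false-positive estimation

Backscattered electrons re-enter the sensor near their primary, creating
an excess of small nearest-neighbour distances between counted events in
ultra-sparse data. `estimate_backscatter_ratio()` histograms per-frame
nearest-neighbour distances in 1-pixel bins to 30 pixels, and fits the
backscatter spawn fraction by least squares over bins 1–15 (where the
excess lives; the bin ranges are free choices) against histograms
simulated at the same event rate for a candidate grid of fractions. The
same seed is reused across candidates (common random numbers) so the
objective is smooth, and the minimum is refined by interpolating the
simulated histograms between grid points. Below a spawn fraction of 0.005
the result is reported as no detectable backscatter; fewer than 1000
events is rejected outright as underpowered. Recovery of an injected
fraction at the published primary-to-backscatter ratio of ~8.6 (used as a
scenario, not as ground truth) is part of the acceptance suite.

For false positives, a dilution series holds the electron flux constant
while the true dose per pixel shrinks geometrically (in practice by
raising magnification); any constant per-pixel false-positive rate then
appears as a floor: `counted_k = d0 * g^k + f`. With the dilution factor
known this is linear in `(d0, f)` and solved by least squares
(`estimate_false_positive_rate()`), with a negative fitted floor clamped
to zero and non-monotone series flagged.

## Numerical and size choices

Simulation problem sizes in the test-suite were chosen so estimates are
statistically decisive at the tolerances asserted: coincidence cells use
100 frames of 1024×1024 (standard errors ~1e-4–5e-4, far inside the 5%
bands); the low-dose limit uses the sparse path at 1e-5 e/pixel/frame
over 30000 frames of 2048×2048 (~1.26M events, so the 3-SE band is about
half the gap between adjacent limit constants); parameter-recovery runs
use 1e5 primaries (backscatter), 5×1e6 pixel-frames (false-positive
floor) and 1000 calibration frames of 32×32 (dark/gain). Bit packing is
LSB-first; binary maps pack in row-major pixel order; on-disk linear
indices are 0-based row-major while the R interface is 1-based (row, col)
throughout, the idiomatic choice for an R package.

## Known limitations

* The container format is self-contained but deliberately not
  byte-compatible with any external tool's format.
* `calibrate_on_the_fly()` assumes the calibration stack is genuinely
  low-dose flat-field data with at least a few electrons per pixel in
  total; calibrating on a handful of frames makes the gain map
  noise-dominated.
* The backscatter estimator assumes the displacement scale of the
  candidate model; it fits the fraction, not the displacement law.
* Throughput is not a goal of this implementation: the parallel pipeline
  demonstrates the part-file/merge contract, not GB/s rates.
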