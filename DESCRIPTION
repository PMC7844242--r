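Package: recode
Title: Reduction and Compression of Electron-Counting Detector Movies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing and losslessly compressing movie-mode data
    from direct electron detectors operated in electron-counting conditions.
    Implements per-pixel signal/noise calibration (fast on-the-fly and fine
    calibration with common-mode correction and puddle-area filtering), four
    data reduction levels (L1 thresholded intensities, L2 per-puddle summary
    statistics, L3 binary maps, L4 counted events), connected-components
    electron-puddle labeling, a pluggable lossless codec layer (deflate,
    zstd, bzip2, lzma, lz4, snappy, with an optional bitshuffle prefilter),
    an indexed on-disk container with parallel part-file writing, merging and
    random frame access, a synthetic electron-event simulator, and analysis
    methods: coincidence-loss estimation, puddle shape statistics and fixed
    polyplet enumeration, reduction/compression benchmarking, backscatter
    ratio and false-positive rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    parallel,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
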