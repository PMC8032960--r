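Package: calwave
Title: Wavelet Ridgewalking and dF/F0 Event Detection for Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Ca2+ transients in single-ROI fluorescence time series
    by two families of methods and quantifies how the choice of method shapes
    downstream analysis.  The first family transforms a trace to dF/F0 under
    three baseline (F0) conventions (initial-window mean, minimal-window mean,
    smoothed sliding 8th percentile) and rasterizes activity under four
    statistical thresholding criteria (2.5 SD or one-sided z-test, referenced
    to either the baseline segment or the whole trace).  The second is a
    continuous wavelet transform with generalized Morse wavelets followed by a
    ridgewalking algorithm whose significance thresholds are calibrated by
    white-noise Monte Carlo modeling at a fixed exclusion rate.  Includes a
    ground-truth synthetic trace simulator (triangular and exponential events
    embedded in white noise and linear bleaching at controlled SNR), detector
    performance scoring against known event bounds, event feature extraction,
    neuropil halo subtraction, and phi-coefficient functional network
    construction with standard binary-graph measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
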