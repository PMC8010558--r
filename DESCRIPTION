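Package: portalcdm
Title: Composite Difference Metric for Real-Time Portal Dosimetry of VMAT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for prompt error detection in
    segment-resolved portal dosimetry of volumetric modulated arc therapy
    (VMAT). Generates synthetic VMAT arc plans, a water-equivalent phantom
    and deliberate delivery errors (monitor-unit scaling, leaf-bank
    retraction, leaf-bank shift, air cavity); predicts electronic portal
    imaging device (EPID) images with an analytic forward model (aperture
    projection, exponential attenuation, couch attenuation, two-Gaussian
    panel scatter, sinusoidal panel sag); computes four running-window image
    difference metrics (central axis signal, mean image value, and mean
    absolute difference relative to maximum and to local predicted
    intensity) and a composite difference metric formed as a weighted power
    sum. Detection thresholds are set by a median-plus-range rule on
    error-free deliveries, and composite-metric weights are optimised by
    exhaustive grid search under leave-pair-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
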