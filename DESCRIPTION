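Package: spherosynergy
Title: Longitudinal Drug-Combination Synergy from Single-Spheroid Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal assessment of two-drug interactions in
    single-spheroid cultures. A simulator generates spheroid growth
    trajectories under a two-drug kill model with tunable synergy and renders
    phase-contrast-like well images with known ground truth. A deterministic
    preprocessing chain (contrast maximization, denoising, margin trimming,
    artifact removal, rescaling) standardizes the images, and a compact
    densely connected convolutional regression network decodes per-well
    viability from endpoint-labelled images so that viability can be
    estimated on unlabelled earlier days. Checkerboard 6x6 dose matrices of
    decoded viability are scored against Loewe additivity, Bliss
    independence and highest-single-agent reference surfaces, with the
    replicate-merging and missing-data rules appropriate for duplicate
    plates, yielding per-day synergy trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
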