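Package: retistitch
Title: Retinal Region Detection and Mosaicing for Smartphone Ophthalmoscope Video
Version: 0.1.0
Authors@R:
    person("retistitch", "maintainers", email = "retistitch@example.org",
           role = c("aut", "cre"))
Description: Classical image-analysis pipeline for low-quality smartphone
    ophthalmoscope (D-Eye style) retinal video. Locates the small bright
    circular retinal window in each frame with a red-channel / Gaussian blur /
    Otsu threshold / contour / Circle Hough Transform chain, crops and pads the
    detected region to a fixed square canvas, and merges overlapping crops into
    a wider-field mosaic by root-SIFT keypoint matching, RANSAC homography
    estimation and distance-transform feathering blending. Includes set-wise
    intensity normalization, bounding-box evaluation metrics (MAE, IoU, class
    binning and summary tables), a seeded synthetic fundus-frame and sequence
    generator with exact ground truth, plain-text PNM image and CSV annotation
    I/O, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
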