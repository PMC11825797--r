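Package: monorow
Title: Monocular Localization of Crop Rows from Depth Maps and Instance Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing and localizing crop rows (such as rolled
    ratoon-rice stubble rows) from a single camera by fusing per-row instance
    masks with metric depth maps. Implements pinhole projection and
    back-projection with intrinsics transforms for image resizing and
    cropping, 16-bit millimetre PNG depth encoding with a zero-as-missing
    convention, the eight masked depth-evaluation metrics standard in
    monocular depth estimation together with the scale-invariant log loss and
    chamfer distance, extraction of banded navigation points and per-row 3D
    point clouds, grid-search calibration of depth predictions migrated
    across cameras (input-resize and output-scale corrections), and a
    synthetic field-scene generator for testing the full pipeline without a
    trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
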