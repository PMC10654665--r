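Package: cephmark
Title: Two-Stage Cephalometric Landmark Detection from Facial Profile Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects 23 cephalometric landmarks on lateral facial profile
    images with a two-stage pipeline: Gaussian heatmap regression by a
    high-resolution multi-branch convolutional network, followed by per-axis
    multilayer-perceptron coordinate refinement that exploits the spatial
    relationships between landmarks. Includes sub-pixel heatmap decoding with
    quarter-pixel offset adjustment, the alternating cycle training schedule,
    evaluation metrics (mean radial error, standard deviation, successful
    detection rate), eight clinical cephalometric measures with three-way
    anatomical face-type classification and successful classification rate,
    a synthetic facial-profile data generator for fully reproducible testing,
    annotation I/O (imglab XML, CSV) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
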