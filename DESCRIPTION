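Package: pinmigrate
Title: Measuring Postoperative Migration of Femoral Fixation Pins from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the postoperative migration of femoral-neck fixation
    pins (e.g. Hansson pins) between two CT-derived 3D models. A partial-femur
    reference is finely registered between the two time points with an
    iterative closest point (ICP) algorithm; the recovered rigid transform is
    transferred to the pin point clouds, and pin displacement and rotation are
    quantified in global, anatomical, and pin-local coordinate frames.
    Includes PCA-based pin axis fitting and oriented-bounding-box endpoint
    extraction with physical length calibration, registration quality metrics,
    a landmark-based femoral coordinate system for the traditional manual
    measurement workflow, readers and writers for common surface formats
    (PLY, STL, OBJ, XYZ), and a seeded synthetic bone-phantom generator with
    known ground-truth transforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
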