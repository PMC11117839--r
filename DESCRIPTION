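Package: scleradic
Title: Stereo Digital Image Correlation Analysis of Posterior Scleral
    Deformation Under Optic Nerve Tethering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying posterior scleral surface
    deformation caused by optic-nerve adduction tethering and intraocular
    pressure elevation.  Implements stereo digital image correlation (3D-DIC)
    with direct linear transformation (DLT) camera calibration and two-view
    triangulation, triangulated-surface area-ratio deformation metrics with
    regional statistics (sectors, annuli and strips around the optic nerve
    sheath), the adduction/tether kinematics of a globe rotating against a
    fixed virtual orbital apex, and uniaxial tensile curve analysis (tangent
    moduli, bilinear log-log toe-region detection, reduced-polynomial
    hyperelastic fitting).  A synthetic-data generator renders speckled
    spherical and planar scenes through pinhole cameras under prescribed
    deformations with exact ground truth, so every stage of the pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
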