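Package: sopal
Title: Stereoscopic Optical Palpation Simulation and Stress Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational pipeline for stereoscopic optical palpation (SOP),
    a tactile-imaging form of optical elastography in which the compression of
    a compliant silicone layer bearing a plane of phosphorescent particles is
    measured by two parallel cameras and converted to a map of surface stress.
    Provides a forward simulator for stereo particle images of deforming
    layers and stiff-inclusion phantoms, windowed normalized least-squares
    disparity matching with sub-pixel refinement, per-pixel disparity to
    thickness calibration with a field-of-view scale model, an algebraic
    Neo-Hookean stress chain (strain from thickness, hyperelastic
    stress-strain law, true-stress conversion), a large-deformation
    axisymmetric and plane-strain Neo-Hookean finite-element solver
    implementing computational optical palpation (displacement-driven
    inversion with regularized Coulomb friction), and the stress-contrast and
    stress-resolution image-quality metrics used to benchmark both methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
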