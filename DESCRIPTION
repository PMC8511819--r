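Package: fracenv
Title: Mechanical Fracture Environment After Intramedullary Nailing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based finite-element pipeline for the mechanical fracture
    environment of a nailed long-bone fracture: synthetic calibrated CT-like
    phantoms of a fractured tibia with an intramedullary nail and a six-rod
    density calibration insert, HU-to-equivalent-mineral-density regression,
    mask-based segmentation, heterogeneous density-elasticity material mapping,
    linear-elastic tetrahedral finite-element solves, and strain-based
    tissue-differentiation (healing-zone) classification with interfragmentary
    movement and per-part von Mises stress reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), oro.nifti, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
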