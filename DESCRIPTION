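Package: sansvex
Title: Virtual Small-Angle Neutron Scattering Experiments and Scattering-Model Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates labelled two-dimensional small-angle neutron scattering
    (SANS) detector images by Monte-Carlo ray tracing of a simplified pinhole
    SANS beamline (modelled on KWS-1 class instruments) over a registry of
    analytic form-factor models with polydispersity and orientational
    averaging, packages the images as machine-learning-ready HDF5/CSV
    partitions, and trains an ensemble of compact convolutional neural
    networks that ranks candidate scattering models for a measured
    two-dimensional pattern (SoftMax-averaged recommendation with Top-k
    accuracy, per-class precision/recall/F1 and confusion-matrix reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rhdf5,
    lhs,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
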