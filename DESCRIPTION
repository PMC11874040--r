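Package: odfscope
Title: Spatio-Angular Modeling and Reconstruction of Dipole Orientation
    Distributions for Polarized Dual-View Light-Sheet Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a polarized dual-view light-sheet microscope that
    recovers per-voxel three-dimensional orientation distribution
    functions (ODFs) of fluorescent dipole ensembles.  Provides real
    spherical-harmonic machinery on even bands (l = 0, 2, 4), physics
    kernels for polarized excitation (cos^2), dipole emission (sin^2),
    finite-NA selective detection and orientation-dependent point spread
    functions, spatio-angular transfer functions, measurement-scheme
    audits for angular holes and condition-number scheme search,
    synthetic ODF phantoms with ground truth, a Fourier-domain forward
    simulator with shot noise, per-spatial-frequency Tikhonov-regularized
    reconstruction, and downstream orientation metrics (GFA, peak
    orientations, parallelism, radiality, aspect ratio, angular
    histograms) together with TIFF/CSV/JSON input and output and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
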