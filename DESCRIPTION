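Package: stinr
Title: Spatiotemporal Implicit Neural Representations for Dynamic Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-shot, self-supervised reconstruction of time-resolved (one volume
    per projection) dynamic cone-beam CT from a single rotating-gantry scan. A
    spatial implicit neural representation (a coordinate MLP with Gaussian random
    Fourier feature encoding) models a reference attenuation volume, while nine
    temporal MLPs model the time-varying weights of a PCA respiratory motion model
    built from a prior 4D image set; both are optimised jointly against the acquired
    projections through a differentiable warp-and-project pipeline. Includes a
    parametric dynamic-thorax phantom with configurable breathing scenarios, a
    ray-driven cone-beam projector with exact adjoint and FDK reconstruction,
    ART+TV and per-projection PCA-weight fitting comparators, a polynomial
    temporal baseline, and an evaluation suite (relative error, DICE, tumor
    center-of-mass error and motion trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    tiff,
    tibble,
    ggplot2,
    rlang,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
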