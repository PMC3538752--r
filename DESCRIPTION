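Package: gstract
Title: Global-Search Tractography, Deterministic Fiber Tracking and
    Fiber-Tract Similarity for Diffusion Tensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs white-matter pathways between two regions of
    interest from diffusion tensor imaging (DTI) data by an A* minimum-cost
    path search over a structured grid, with a cost that combines the
    directional propagation probability of the diffusion tensor, the
    divergence from the principal diffusion direction and fractional
    anisotropy.  Also provides the deterministic reference trackers
    (fourth-order Runge-Kutta streamline propagation and tensor deflection),
    an adaptive ROI-padding / FA-relaxation reconstruction protocol, a
    fiber-tract similarity framework based on trimmed closest-point
    distances and FA sampling, and a DTI software-phantom simulator
    (straight, branching, kissing and spiral bundles with Rician noise)
    that makes the whole system verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
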