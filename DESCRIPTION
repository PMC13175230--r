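Package: ivimtools
Title: Consensus Acquisition Design and Fitting for Intravoxel Incoherent
    Motion (IVIM) Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing intravoxel incoherent motion
    (IVIM) diffusion-weighted MRI studies along community-consensus lines:
    the biexponential perfusion/diffusion forward model with Gaussian or
    Rician noise, iterative weighted-linear and segmented fitting routines,
    simultaneous nonlinear least-squares fitting, organ-specific b-value
    tiers and acquisition presets with a protocol compliance checker and
    reporting checklist, Cramer-Rao lower-bound b-value optimization,
    Monte Carlo SNR planning, digital phantom generation, NIfTI/FSL
    gradient-table I/O, and standardized region-of-interest reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
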