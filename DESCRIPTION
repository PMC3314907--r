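Package: lpfdti
Title: Local Perturbation Field Estimation and Correction for Diffusion
    Tensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatially varying first-order perturbations of the
    diffusion-weighting gradients (eddy currents, gradient nonuniformity,
    mis-calibration, concomitant and cross terms) from isotropic water-phantom
    diffusion-weighted MRI, models the perturbation as a local perturbation
    field (LPF) matrix expanded in third-order real solid spherical harmonics,
    predicts the resulting bias on diffusion tensor index maps (mean
    diffusivity, fractional anisotropy) through the LPF ellipsoid, and corrects
    measured diffusion tensors using the diagonal or the full estimated LPF
    matrix. Includes a synthetic-phantom simulator and a Monte-Carlo study of
    estimator precision, plus NIfTI/bval/bvec input-output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
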