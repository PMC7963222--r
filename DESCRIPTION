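Package: qtimcd
Title: Tensor-Valued Diffusion MRI Differentiation of Cortex and White
    Matter in Malformations of Cortical Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the q-space trajectory imaging (QTI) cumulant model to
    tensor-valued diffusion MRI data by voxel-wise heteroscedasticity
    corrected linear regression, and derives scalar maps of mean diffusivity,
    fractional anisotropy and microstructural kurtosis metrics, including
    the anisotropic (microscopic) kurtosis MK_A that separates microscopic
    diffusion anisotropy from orientation coherence. Includes a digital
    phantom of malformations of cortical development with ground-truth
    diffusion tensor distributions, Rician-noise signal simulation and
    pseudo-structural contrasts, the associated preprocessing (discrete
    Gaussian smoothing, cerebrospinal-fluid voxel exclusion), and an
    ROC-threshold voxel-classification back end that reports per-lesion
    white-matter-like percentages by contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
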