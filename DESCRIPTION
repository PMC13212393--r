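Package: mrcytometry
Title: Microstructural MR Cytometry from Time-Dependent Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward models, simulation, preprocessing, voxelwise fitting and
    cohort statistics for MR cytometry with combined oscillating-gradient
    (OGSE) and pulsed-gradient (PGSE) spin-echo diffusion MRI. Implements the
    restricted-diffusion Gaussian-phase-distribution signal for impermeable
    spheres, the IMPULSED two-compartment model, the Kaerger transcytolemmal
    water-exchange model (JOINT) and a discretized arbitrary-waveform exchange
    integrator (EXCHANGE), together with a random-walk Monte-Carlo oracle,
    MP-PCA denoising, IVIM removal, time-dependent ADC fitting, two-group
    phantom cohorts with Rician noise, and the ROC / logistic-regression /
    DeLong machinery used to discriminate tumour groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    minpack.lm,
    pROC,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
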