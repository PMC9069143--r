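Package: steDWI
Title: Spherical Versus Linear Tensor Encoding DWI: Lesion Conspicuity
    Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study why high b-value diffusion-weighted imaging with
    spherical b-tensor encoding (STE) suppresses white matter and improves the
    conspicuity of glioma hyperintensities compared with conventional linear
    encoding (LTE) averaged over directions. Provides b-tensor and acquisition
    protocol constructors, a multi-compartment Gaussian forward model with
    Watson orientation dispersion, T2 weighting and powder averaging, a 3-D
    digital glioma phantom with Rician magnitude noise, region-of-interest
    conspicuity statistics (signal intensity ratio, contrast-to-noise ratio
    efficiency, per-acquisition noise estimation), cohort-level nonparametric
    statistics, and NIfTI based input/output with a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
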