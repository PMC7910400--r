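Package: petiq
Title: Image-Quality Metrics and Reference-Region Kinetics for Brain PET
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative cross-validation of PET scanners with a
    focus on brain imaging. Simulates a digital contrast phantom (warm
    cylinder with hot and cold spheres, scanner-like Gaussian point spread
    function, count-dependent noise) with analytic ground truth, implements
    the NEMA-style image-quality analysis (hot/cold sphere recovery
    coefficients, percent background variability from 60 background regions
    per sphere size, voxel-level noise, recovery-versus-noise iteration
    trajectories, line profiles), simulates reference and target-region
    time-activity curves with a simplified reference tissue forward model,
    quantifies binding with reference-region Logan graphical analysis and
    late-window activity ratios, and produces cross-scanner comparison
    reports. Images are read and written as NIfTI-1, results as tidy CSV
    tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
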