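Package: aortaflow
Title: Automated Batch Analysis of Aortic 4D Flow MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, spreadsheet-driven batch processing of
    time-resolved three-dimensional phase-contrast (4D flow) MRI of the
    thoracic aorta. Imports classic single-frame DICOM series or a
    compressed HDF5 container, applies threshold-based noise masking,
    polynomial background phase-offset correction and fixed-iteration
    velocity anti-aliasing, derives an aortic centerline with analysis
    planes from a 3D segmentation, and quantifies regional peak velocity,
    kinetic energy and viscous energy loss together with global pulse wave
    velocity from cross-correlated flow-time curves. A curved-tube pulsatile
    phantom generator with analytic ground truth supports end-to-end
    validation, and deterministic quality-check rasters document every run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    RNifti,
    igraph,
    png,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
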