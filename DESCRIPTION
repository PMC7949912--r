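Package: sliceage
Title: Slice-Level Brain-Age Prediction with Inverse-Error Ensembling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts brain age from segmented structural MRI one 2D slice at a
    time. Independent per-orientation (axial, coronal, sagittal) convolutional
    slice regressors produce a vector of per-slice age estimates for each
    subject; a per-view linear regression combines the slice estimates, and the
    three views are merged by an inverse-validation-error weighted average.
    Includes per-slice error profiling with confidence bands, voxel-level
    brain-age maps with Gaussian smoothing, age/site/sex bias diagnostics, and
    a synthetic aging-brain phantom generator so the whole pipeline runs and is
    testable on a desktop CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
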