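Package: dermavol
Title: 3D Photogrammetric Morphometry of Skin Lesions and Photodynamic
    Therapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying basal cell carcinoma (BCC)
    lesions from 3D surface reconstructions represented as raster height
    maps. Fits a reference skin plane to a background region of interest,
    integrates cut-and-fill volumes to obtain absolute volume (3DAbsVol)
    and average height (3DAvHt), calibrates volumes against physical
    phantoms of known mass, classifies five-visit lesion trajectories as
    cleared or not cleared against a normal-skin background threshold, and
    sweeps baseline size thresholds to find the operating point where
    sensitivity and specificity of predicting photodynamic therapy (PDT)
    response are approximately equal. Includes a synthetic-data generator
    (skin surfaces, lesion caps and ulcers, hemispherical phantoms, visit
    trajectories, cohorts) so the whole pipeline is testable without
    clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
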