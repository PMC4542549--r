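Package: splenotex
Title: Three-Dimensional Grey-Level Co-Occurrence Texture and Volumetry
    for Optical-CT Spleen Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of optical computed-tomography image
    volumes of murine spleen. Implements a three-reference-point 3-D
    grey-level co-occurrence matrix (GLCM) and its contrast and
    homogeneity texture features, displacement sweeps with angular
    averaging and sub-sample peak localisation, sparse-keyframe contour
    volumetry with signed-distance interpolation, exact small-sample
    one-tailed Mann-Whitney U tests, and a synthetic spleen-phantom
    generator emulating red pulp, white-pulp nodules, marginal zones,
    vessels, noise and streak artifacts for vehicle and treated cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
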