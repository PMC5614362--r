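Package: srvox
Title: Super-Region Segmentation of Volumetric Bioimaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless, scriptable toolkit for semi-automatic segmentation of
    3D tomography volumes (cryo electron tomography, cryo soft X-ray
    tomography, X-ray micro-tomography). Provides volume I/O (HDF5, MRC, TIFF),
    derived feature channels (Gaussian-family filters, total-variation
    denoising, blob and texture detectors), a two-tier super-region hierarchy
    (SLIC-style 3D supervoxels and graph-merged megavoxels), scribble-trained
    classifier segmentation with confidence-based label commitment and Markov
    random field refinement, morphological label cleanup, rule-based splitting
    of segmented objects with per-object morphometry, and ground-truthed
    synthetic phantom generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    e1071,
    glmnet,
    tiff,
    rhdf5,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
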