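Package: heartseg4d
Title: Atlas-Based Whole-Heart Segmentation for Respiratory-Binned 4D-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-atlas automatic segmentation of the whole heart on
    respiratory-binned four-dimensional computed tomography, for motion-aware
    organ-at-risk contouring in lung radiotherapy. Implements lung-based
    cropping of a heart volume of interest, two-step rigid plus Thirion
    demons deformable registration, consensus-based rejection of discordant
    atlases, local-weighted label fusion, propagation of the end-exhale
    delineation across breathing phases, construction of the
    motion-encompassing planning organ-at-risk volume as the union of
    per-phase delineations, and surface-distance evaluation metrics (Dice,
    mean absolute surface distance, Hausdorff distance). Includes a
    parametric 4D thorax phantom cohort generator with ground truth for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
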