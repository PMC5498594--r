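Package: cortigap
Title: Detection and Cross-Modality Matching of Cortical Interruptions in 3D CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated detection, sizing and cross-modality matching of
    cortical interruptions (erosions, pores) in 3D CT volumes of peri-articular
    bone. Implements periosteal auto-contouring, modality-specific bone
    segmentation (Laplace-Hamming and Gaussian filtering), a constant-thickness
    cortical mask, the five-step dilation algorithm that detects interruptions
    exceeding a minimum opening diameter, rigid multi-resolution registration
    with label resampling and voxel-overlap matching between a low-resolution
    (HR-pQCT class, 82 um) and a high-resolution (micro-CT class, 18 um)
    acquisition of the same bone, and the reliability-statistics layer
    (two-way random absolute-agreement ICC, exact Wilcoxon signed-rank,
    lesion-level positive predictive value and sensitivity). A synthetic
    phantom generator produces paired volumes with known ground truth so the
    whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
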