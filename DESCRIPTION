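Package: ctwml
Title: White Matter Lesion Segmentation from Head CT with Cross-Modality Trained Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated volumetric assessment of white matter lesions
    (WML) from non-contrast head CT. Implements the full pipeline: NIfTI volume
    handling and resampling, brain extraction, 9-degree-of-freedom spatial
    normalization of brain masks, rigid CT-to-FLAIR registration by normalized
    mutual information, z-score intensity normalization, a patch-based residual
    U-shaped convolutional network trained with FLAIR-derived lesion labels,
    a repeated cross-validation ensemble that averages per-subject probability
    maps before thresholding, and evaluation machinery (Dice overlap, volume
    correlation, Bland-Altman agreement, and volume-threshold Fazekas grading
    with cross-validated confusion matrices). A paired pseudo-FLAIR/pseudo-CT
    phantom generator provides reproducible synthetic cohorts spanning three
    Fazekas severity strata for development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
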