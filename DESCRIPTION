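Package: icbmri
Title: Volumetric Response Criteria and Radiomic Response Prediction for
    Preclinical Glioma Immunotherapy MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for serial MRI response assessment of preclinical
    (mouse) gliomas under immune-checkpoint blockade: a volumetric
    translation of the RANO/iRANO criteria with pseudoprogression rescue
    and growth-pattern calls, a frozen 423-feature 3D radiomic extractor
    (first-order, shape, texture, curvature) with longitudinal delta
    features, an in-package gradient-boosted classifier evaluated by
    repeated stratified cross-validation against the no-information rate,
    small immunology statistics (geometric-mean gene-signature scores,
    immunogram z-scores, TCR clonality, shared CDR3 motifs, LDH specific
    lysis), and a seeded synthetic 3D tumor-cohort generator for
    end-to-end testing without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
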