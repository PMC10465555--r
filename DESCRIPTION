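Package: emphysemap
Title: Weakly-Supervised Emphysema Subtyping and Quantification on Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates Fleischner-style visual scoring of centrilobular and
    paraseptal emphysema on thoracic CT. A 3D ResNet backbone with a
    reconstruction (decoder) network is trained weakly: ordinal severity
    scores are converted to per-lung emphysema-percentage intervals and
    optimized with an interval-regression loss, a mutual-exclusion
    (soft-Dice overlap) loss between subtype probability maps, and a
    segmentation loss against LAA-950 low-attenuation pseudo-labels. The
    package provides CT/mask preprocessing, a synthetic lung-phantom
    generator for fully reproducible experiments, training and inference
    with dense regression activation maps, and the agreement statistics
    (accuracy, macro F-measure, linear weighted kappa with confidence
    intervals) used to compare predicted and visual scores.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
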