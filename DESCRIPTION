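Package: noseguard
Title: Nose-Preserving MRI De-Identification and MEG-MRI Coregistration Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de-identifying T1-weighted structural MRI volumes while
    preserving the nose ("face trimming"), together with the machinery needed
    to evaluate the consequences for MEG-MRI coregistration and forward-model
    surfaces: rigid landmark and iterative-closest-point head-shape
    registration, a simplified atlas (affine plus demons-style nonlinear)
    registration with face-class tissue labeling, scalp-surface extraction,
    canonical inner-skull template-mesh warping, vertex-wise surface
    comparison, paired nonparametric statistics and JZS Bayes factors, and a
    synthetic head-phantom generator providing known ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
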