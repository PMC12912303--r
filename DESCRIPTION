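Package: ecgexperts
Title: Multi-Expert Hierarchical Multi-Label Learning for 12-Lead ECG Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hierarchical multi-label classification of 12-lead electrocardiograms
    with label-correlation matrices (conditional, mutually exclusive, mutually
    symbiotic), a family of twelve expert losses built from sigmoid and local
    softmax activations with long-tailed, balanced and inverse logit adjustments,
    a symbiotic ranking regularizer enforcing parent-over-child prediction order,
    a multi-scale one-dimensional residual network in private- and shared-backbone
    ensemble schemes with averaging aggregation, the matching label-wise and
    exam-wise evaluation protocol (AUROC, average precision, break-even
    thresholding, consistency diagnostics, Bland-Altman and paired t-tests), and a
    seeded synthetic ECG generator so the whole pipeline is exercisable end to end
    without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
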