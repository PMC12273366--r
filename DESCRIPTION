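Package: rfed
Title: Robust Federated Learning for Multicenter Class-Imbalanced Lesion-Image Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and trains a personalized federated learning framework for
    multicenter, class-imbalanced lesion-image prognosis. Clients exchange model
    parameters through Fourier-domain partial aggregation in which amplitude and
    phase spectra are averaged and only a progressively widening low-frequency
    band is shared, while a three-stage transfer schedule gated by validation AUC
    moves knowledge between each center's deputy and personalized models. Local
    objectives combine a margin-calibrated cross-entropy for class imbalance with
    a contrastive alignment term between local and global classifier-layer
    parameters. Downstream prognosis uses convolutional-channel features pooled
    per patient, minimum-redundancy maximum-relevance feature selection, and a
    Bayesian extreme learning machine, evaluated by ROC AUC, F1, sensitivity at
    fixed specificity and decision-curve net benefit. Includes a seeded generator
    of heterogeneous multicenter synthetic lesion images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
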