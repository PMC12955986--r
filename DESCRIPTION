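Package: defnet
Title: Divergent Emotional Functional Networks from Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of naturalistic-paradigm fMRI ROI time series.
    Stage one estimates recurring dynamic functional-connectivity brain states
    by sliding-window correlation and two-step L1 k-means clustering, decodes
    two emotion conditions with leave-one-subject-out ReliefF + linear SVM
    models over state-combination feature sets, and summarises the stable
    discriminative features as per-network-pair weights (divergent emotional
    functional networks, DEFN). Stage two transfers those weights as ranked
    feature masks into a nested cross-validated patient-versus-control
    classifier on static connectivity, with in-fold age/sex confound
    regression, a whole-brain baseline and McNemar comparison. Includes a
    synthetic-cohort generator with planted latent states and network-pair
    group effects, and the supporting statistical kernel (pooled t, chi-square,
    paired t, Wilcoxon signed-rank, Lilliefors gate, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    e1071,
    nortest,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
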