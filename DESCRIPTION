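Package: couchshift
Title: Patient-Trajectory Clustering and Baseline Rectal-Volume Cutoffs for
    Radiotherapy Setup-Error Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of per-patient cone-beam CT (CBCT) session
    trajectories in prostate radiotherapy. Stage 1 embeds variable-length,
    standardized sequences of rectal-volume change, couch-displacement
    magnitude and rectal volume with a masked Transformer autoencoder
    (implemented natively, trained by Adam on masked reconstruction MSE with
    grouped 5-fold cross-validation). Stage 2 clusters the patient embeddings
    with K-means, canonicalizes clusters by median baseline rectal volume,
    and derives a baseline rectal-volume risk cutoff by ROC analysis with
    Youden's index, alongside the nonparametric test chain (Shapiro-Wilk,
    Spearman, Kruskal-Wallis, pairwise Mann-Whitney U with Bonferroni
    correction). Includes a synthetic cohort simulator with planted patient
    groups and known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
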