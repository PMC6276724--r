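Package: morphoclass
Title: SVM Classification and Statistical Screening of Regional Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for case-control studies of
    regional brain morphometry and white-matter connectivity. Generates
    synthetic diagnosis-by-sex cohorts with regional feature tables and toy
    cortical geometry; computes vertex-wise connectivity density from
    streamline sets on triangulated meshes; reduces feature tables with PCA
    under a variance-retention rule; classifies subjects with a from-scratch
    SMO-trained kernel support vector machine using class-weighted box
    constraints and one-vs-one multiclass voting; summarizes repeated
    k-fold cross-validation with confusion matrices and tensors; screens
    features a posteriori with Welch tests, four-group ANOVA and
    Benjamini-Hochberg false-discovery-rate control; and embeds cohorts
    with classical multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    yaml
Config/testthat/edition: 3
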