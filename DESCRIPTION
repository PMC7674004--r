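Package: octamls
Title: Multilayer and Multisector Peripapillary OCTA Analysis for Glaucoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying peripapillary microvascular density from
    en-face optical coherence tomography angiography (OCTA) and classifying
    glaucoma from it. Covers fovea-disc axis correction from annotated fundus
    images, percentile-threshold segmentation of macrovessels and of the optic
    nerve head optically hollow area, Garway-Heath sectorization into a
    6-layer x 7-sector grid of microvascular intensity medians (VIM), nested
    leave-one-out cross-validation with univariate feature selection over
    SVM, random-forest and gradient-boosting classifiers, and the matching
    statistical suite (Mann-Whitney, Kruskal-Wallis, permutation ANOVA with
    FDR post hoc, DeLong, McNemar-Bowker, stratified bootstrap confidence
    intervals). A seeded phantom generator provides cohorts with controllable
    disease effects so every stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    quadprog,
    png,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
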