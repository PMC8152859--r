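Package: bodyrsa
Title: Representational Similarity Analysis of Body-Part Coding in
    Occipitotemporal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for block-design fMRI analysis of body-part
    category coding: synthetic cohort simulation with a planted three-cluster
    representational geometry, first-level general linear model estimation with
    a canonical double-gamma haemodynamic response, discrete-cosine high-pass
    filtering and pooled AR(1) whitening, sphere-ROI activation detection,
    split-half (1 - r) representational dissimilarity matrices, analysis of
    similarities (ANOSIM) with the complete 420-partition permutation null,
    Mantel tests, three-class linear support-vector decoding with
    leave-one-run-out cross-validation and balanced bootstrap subsampling, and
    the accompanying group and trait statistics (chi-square with Cramer's V,
    Welch and Student t-tests with Cohen's d, mixed-design ANOVA with partial
    eta squared and covariate adjustment, Bonferroni-corrected Spearman
    correlations, partial correlation, framewise displacement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    RNifti
Config/testthat/edition: 3
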