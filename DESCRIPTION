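Package: fmricpca
Title: Task-Based Multivariate Functional Connectivity by Constrained PCA of fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts shared task-related functional brain networks from
    multi-subject event-related fMRI by constrained principal component
    analysis: finite impulse response (FIR) design matrices are fit by
    multivariate regression, the predicted (task-related) portion of the
    BOLD signal is decomposed by SVD with varimax rotation, and
    subject- and condition-specific predictor weights trace estimated
    hemodynamic responses. Includes mixed-design ANOVA on predictor
    weights with Greenhouse-Geisser sphericity correction and FDR-adjusted
    simple effects, within-network voxelwise group inference by
    permutation testing with threshold-free cluster enhancement (TFCE)
    and family-wise error control, lesion overlap and Dice similarity
    utilities, behavioral composite scoring by PCA, brain-behavior
    correlation, and a seeded synthetic-data generator emulating a
    two-group isometric hand-grip study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
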