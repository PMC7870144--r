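Package: neuromaturation
Title: Quantitative Maturation Analysis of Induced Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the maturation of induced neurons across
    species and differentiation time: neurite morphometry from traced
    reconstructions (SWC and Imaris-style HOC), including Sholl analysis,
    polarity classification, longest-neurite axon identification and
    per-batch normalization; whole-cell patch-clamp feature extraction
    (passive membrane properties from voltage steps and ramps, action
    potential counting, scaled-template detection of spontaneous EPSCs);
    single-cell count-matrix quality control, Wilcoxon differential
    expression and exact-binomial / Fisher gene-set enrichment; the group
    statistics tying the stages together (Mann-Whitney U with an exact
    enumeration path, Welch t, Shapiro screen, type-II two-way ANOVA); and
    ground-truthed synthetic-data generators for every stage so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
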