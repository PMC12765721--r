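Package: plaquemetry
Title: Volumetric and Planimetric Quantification of Dental Plaque from
    Sequential Intraoral Scans
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies de-novo dental plaque from paired intraoral scans
    (clean baseline and plaque-bearing follow-up) of the same tooth
    surfaces. Provides triangulated surface-mesh input/output (PLY, STL,
    OBJ), robust trimmed point-to-plane best-fit superimposition of
    region-of-interest pairs, signed plaque-thickness fields, the
    Volumetric Plaque Index (VPI) and area-Adjusted VPI (AVPI),
    colour-coded and Boolean orthographic thickness maps with planimetric
    coverage (PLANIvolmap), trainable pixel classification of two-tone
    disclosed-plaque images (PLANItot/PLANIdark/PLANIlight),
    Turesky-modified Quigley-Hein Plaque Index (TMQHPlI) aggregation, and
    the full method-comparison statistical toolbox (Shapiro-Wilk,
    Friedman, Wilcoxon with Bonferroni correction, Spearman,
    Passing-Bablok regression on z-scores, ROC analysis, segmented
    growth-regime regression). A synthetic tooth-surface simulator with
    analytic ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    png,
    tiff,
    EBImage,
    randomForest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
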