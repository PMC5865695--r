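Package: dtameta
Title: Diagnostic Test Accuracy Meta-Analysis with Summary ROC and
    Detection-Rate Pooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of diagnostic test accuracy studies:
    per-study 2x2 accuracy metrics with exact confidence intervals,
    fixed-effect and DerSimonian-Laird random-effects pooling with Cochran Q
    and I-squared heterogeneity statistics, Moses-Littenberg summary ROC
    regression with AUC and the Q* index, logit-scale pooling of detection
    rates (proportions) by covariate stratum, subgroup Z comparisons,
    leave-one-out sensitivity analysis, and Deeks' effective-sample-size
    funnel-plot asymmetry test for publication bias. Includes seeded
    generators of synthetic study-level datasets for simulation studies and
    a pipeline that assembles the full analysis into report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
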