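Package: epimarker
Title: Correlation-Cascade Discovery of Developmental Surface Markers in Staged RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen staged bulk RNA-seq expression data for cell-surface
    markers of an "active" developmental state, modelled on the fetal epicardium.
    Implements an anchor-gene Pearson correlation cascade with surfaceome,
    differential-expression, endothelial-exclusion, fold-change, confirmation and
    adult-silencing filters; a replicate-based nonparametric (M,D) differential
    expression statistic; upstream transcription-factor prioritization by promoter
    position-weight-matrix scanning with min-max relative binding scores; sample
    structure analyses (PCA, agglomerative clustering with Manhattan distances,
    k-means); and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
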