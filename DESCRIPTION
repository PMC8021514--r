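Package: pdacmeth
Title: Genome-Wide DNA Methylation Analysis and Early-Recurrence
    Prediction for Pancreatic Ductal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Infinium 450K beta-value methylation
    cohorts of pancreatic ductal adenocarcinoma: detection p-value and
    sex-chromosome probe filtering, two-group differential methylation
    screens (Welch's t with optional Bonferroni correction and a
    delta-beta effect-size filter), principal component analysis and
    Ward hierarchical clustering of tumours, and construction of a
    multi-CpG voting panel that predicts early recurrence after
    surgery from per-CpG ROC/Youden cut-offs with directional calls
    and a k-of-n rule.  Includes Kaplan-Meier/log-rank survival
    comparison, pyrosequencing replicate merging and platform
    concordance checks, and a synthetic-cohort simulator with planted
    ground truth so every stage can be exercised and benchmarked
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
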