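Package: intermir
Title: Integrative miRNA-mRNA Expression Analysis for Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for paired miRNA and mRNA
    expression profiles from tumor versus non-neoplastic tissue cohorts.
    Provides two-group differential expression with Benjamini-Hochberg false
    discovery rate control and signed fold changes, interaction-constrained
    miRNA-target integration with Spearman anti-correlation filtering,
    hierarchical sample clustering with the 1-minus-correlation metric,
    AUC-ranked SVM biomarker classifiers assessed by leave-one-out
    cross-validation, clinical association screening, median-dichotomized
    Kaplan-Meier survival analysis, Pfaffl-model relative quantification of
    RT-qPCR data, and a synthetic cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    e1071,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
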