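Package: mirnaprog
Title: Analytical Validation and Prognostic Classification for FFPE miRNA Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical validation of probe-level miRNA
    microarray assays on formalin-fixed paraffin-embedded (FFPE) tumour
    specimens, and for a t-statistic/SVM recurrence prognosticator evaluated
    by Monte-Carlo and nested leave-one-out cross-validation. Includes a
    calibrated synthetic-cohort generator with analytical-condition
    perturbations (RNA input amount, ATP-mix dilution, chip lot, RNA
    extraction and labeling kits), per-array QC metrics with
    background-based detection calls, probe-set summarization (raw
    average-difference and an RMA-style quantile/median-polish pipeline),
    principal-component quantification of between-kit variance,
    prognosticator-call robustness reports, and Kaplan-Meier/log-rank
    survival separation of predicted groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    limma,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
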