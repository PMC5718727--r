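Package: pathcea
Title: Cost-Effectiveness Analysis of Sequential Prostate Cancer Diagnostic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates and exactly evaluates sequential diagnostic strategies
    for clinically significant prostate cancer built from multiparametric MRI
    (MPMRI), transrectal ultrasound-guided biopsy (TRUSB) and template prostate
    mapping biopsy (TPMB), using subgroup-conditional test-performance tables
    and an exact decision-tree engine. Attaches lifetime outcomes through a
    discrete-time cohort Markov model whose transition probabilities can be
    calibrated to survival and metastasis targets, and ranks strategies on
    detection-per-pound and cost-per-QALY efficiency frontiers with incremental
    cost-effectiveness ratios, net-benefit analysis, and probabilistic
    sensitivity analysis (cost-effectiveness acceptability curves and frontier
    membership probabilities). Ships transcriptions of published
    test-performance tables and a synthetic parameter generator so the full
    pipeline is testable without access to individual-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
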