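Package: icar
Title: Functionality Scoring of PD-1 Ligands from Reporter-Cell Blocking Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the functional engagement of PD-1 by its ligands (PD-L1,
    PD-L2) from raw 96-well reporter-cell blocking-assay plate measurements,
    and carries the scores through a clinical evaluation pipeline: responder
    classification (RECIST), cutoff-based cohort stratification, contingency
    and rank-sum comparisons, Kaplan-Meier survival with log-rank tests,
    response-duration summaries, Combined Positive Score (CPS) computation,
    and a cross-validated single-round boosted-tree evaluation of predictive
    power under cohort subsampling. Includes a synthetic plate-and-cohort
    generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    xgboost,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
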