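Package: ghrskit
Title: Diagnostic Modelling and Network Biology for Gastrointestinal Heat
    Retention Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for characterizing a clinical
    syndrome from expert consensus through network biology: Delphi item
    screening with coefficient-of-variation and full-mark-rate deletion
    rules and Cronbach's alpha; cohort description with Pearson chi-square
    group comparisons; core-symptom selection by L1-penalized logistic
    regression with the cross-validated one-standard-error lambda rule;
    a gradient-boosted-tree diagnostic model with grid-searched parameters,
    an error-minimizing probability threshold, five diagnostic rates, ROC
    and AUC, and gain-based feature importance; phenotype-term gene mapping,
    interaction-subgraph topology, median-degree hub filtering and
    hypergeometric gene-set enrichment; and assembly of a tripartite
    symptom-gene-pathway network. Includes seeded generators for every
    input the pipeline consumes (expert Likert score matrices, clinical
    cohorts with known ground truth, and knowledge-base snapshots), so the
    whole pipeline is testable against planted truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    xgboost,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
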