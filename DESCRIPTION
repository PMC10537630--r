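Package: mnqsar
Title: Chemotype Enrichment and Imbalance-Aware QSAR Modeling for
    Micronucleus Genotoxicity Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for binary structure-activity modeling of
    micronucleus (MN) assay outcomes in vitro and in vivo: curation of
    chemical records (salt stripping, neutralization, InChIKey
    deduplication with conflict policies), chemotype enrichment analysis
    (per-substructure 2x2 contingency statistics, one-sided Fisher exact
    tests, odds-ratio and significance filtering, rule-based set-level
    prediction, cross-endpoint relevance tiers), descriptor and
    fingerprint featurization with correlation prefiltering and genetic
    algorithm subset selection, class weighting and SMOTE oversampling
    for imbalanced labels, and random forest / SVM / gradient boosting
    classifiers with stratified shuffle-split cross-validation, Butina
    cluster splits and majority-vote ensembling. Includes a synthetic
    data generator that plants enriched substructures at controlled
    class-conditional prevalences so the whole pipeline is testable
    without proprietary datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    e1071,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
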