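Package: cohortshift
Title: Detection and Semantic Characterization of Temporal Drifts in
    Health Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-stage workflow for analysing temporal data drifts in
    patient cohorts. Stage one monitors divergence between temporal chunks
    of a cohort with five complementary metrics (Jensen-Shannon divergence,
    centroid cosine distance, PCA and autoencoder reconstruction errors,
    and a two-chunk domain-classifier score), normalizes the resulting
    signals and flags drifts with a k-standard-deviation rule. Stage two
    characterizes what changed globally: outcome prevalence, per-chunk
    feature-outcome correlations, tree-ensemble feature importances and
    outcome-class centroid trajectories. Stage three explains drifts
    semantically: patient event sequences (or bipartite patient-attribute
    graphs for snapshot data) are embedded with a seeded skip-gram model in
    which the outcome is encoded as one artificial token per temporal
    chunk, so changes in cosine similarity between clinical tokens and the
    outcome can be ranked and aggregated by ICD-like chapter. A seeded
    synthetic cohort generator with injectable sudden, incremental, gradual
    and reoccurring drifts makes the whole pipeline testable without
    access to credentialed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    igraph,
    cluster,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
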