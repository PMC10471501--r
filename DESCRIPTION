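Package: normhet
Title: Normative Modelling and Multiscale Heterogeneity Mapping of
    Regional Brain Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits hierarchical normative models of regional brain
    phenotypes (for example grey-matter volume) on multi-site reference
    cohorts with partial pooling of site- and sex-specific intercepts,
    age slopes and noise scales, and scores held-out individuals as
    deviation z-maps. Person-specific extreme deviations are then
    aggregated at three spatial scales: regional overlap maps,
    circuit-level overlap via normative seed-based functional
    connectivity (one-sample t, threshold-free cluster enhancement on
    grayordinate graphs, max-statistic family-wise error control), and
    functional-network overlap. Case-control overlap differences are
    tested under two permutation null models -- group-label exchange and
    spatial spin surrogates (Hungarian assignment on the sphere) that
    preserve each person's deviation burden -- with generalized Pareto
    tail approximation of permutation p-values and Benjamini-Hochberg
    correction. A synthetic-cohort generator (parcellation, multi-site
    phenotype cohort, functional-connectivity atlas, configurable
    deviation scenarios) makes the full pipeline testable without
    access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
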