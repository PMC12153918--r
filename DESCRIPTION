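Package: milkstate
Title: Herd-State Monitoring from Bulk-Tank Milk Fatty-Acid Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to monitor dairy-herd status from mid-infrared-predicted
    fatty-acid profiles of bulk tank milk. Implements the full analysis
    chain used for milk-payment monitoring data: record cleaning under
    ICAR-style bounds, conversion of fatty acids to a g/100 g fat basis,
    principal-component reference projection with standardized Mahalanobis
    (GH) novelty scoring, GH-stratified subsampling, Ward.D2 hierarchical
    clustering with dendrogram-gap selection of the number of herd states,
    supervised re-prediction of states by PLS-DA and random forest with
    cross-validated accuracy and Cohen's kappa, Markov transition-matrix
    estimation between states, temperature-humidity-index (THI) weather
    enrichment, and a traffic-light alert layer over state-membership
    probability time series. A synthetic-data module generates bulk-tank
    time series with the assumed statistical structure (latent Markov
    states with Gaussian trait profiles, irregular 1-3 day sampling,
    realistic data artifacts) so the whole pipeline is testable without
    access to proprietary milk-payment records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    randomForest,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
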