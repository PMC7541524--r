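Package: tradeflow
Title: Longitudinal Dyadic Mixed-Effects Models and Cluster Analysis for
    Bilateral Trade Networks
Version: 0.1.0
Authors@R:
    person("Trade", "Flow Developers", email = "maintainer@tradeflow.dev",
           role = c("aut", "cre"))
Description: Tools for assembling, modelling and summarising longitudinal
    directed weighted trade networks. Reads and reconciles bilateral trade
    matrices (exporter- and importer-reported flows), zero-fills and filters
    country panels, builds gravity-model design matrices, fits a Bayesian
    longitudinal mixed-effects dyadic network model with sender/receiver
    random effects following VAR(1) dynamics and AR(1) reciprocity-correlated
    dyadic residuals via a Gibbs/Metropolis sampler, detects communities in
    yearly directed weighted networks (exact, greedy and random-walk based
    modularity optimisation, k-core decomposition), and quantifies robustness
    of inference via the replacement-of-cases framework. Ships a synthetic
    data generator so the full pipeline is testable end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
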