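Package: aacddm
Title: Affective Drift Diffusion Modeling of Approach-Avoidance Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative and inferential tools for an affective drift diffusion
    model (DDM) of approach-avoidance conflict decisions. Trial-level drift
    rate, boundary separation and starting point are linear functions of
    offered reward and aversiveness, a Pavlovian response-mapping dummy and
    trial-by-trial region-of-interest (ROI) activity. Provides the Wiener
    first-passage-time likelihood with small-time/large-time series expansions,
    a stochastic trial simulator, a task and dataset generator for simulation
    studies, hierarchical Bayesian estimation by adaptive MCMC with
    Gelman-Rubin diagnostics and DIC model comparison, posterior group
    comparisons with highest density intervals, posterior predictive checks,
    two-way intraclass correlations for test-retest reliability, and
    cross-validated regularized logistic classification of clinical status
    from individual parameter estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
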