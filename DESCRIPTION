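Package: cardiotag
Title: Heart-Rate Biologging QC and Bayesian Threshold Poisson Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for archival heart-rate tag deployments on
    large fish. Provides a synthetic-data generator emulating an 80-day
    cage deployment (10-minute logger records with quality indices,
    peripheral temperature, activity, and a daily feeding log), burst-level
    signal metrics (ECG R-peak detection and heart rate, external
    acceleration activity), record-level quality control and daily
    aggregation, and the core estimator: identity-link Poisson regression
    of daily median heart rate on temperature, feeding and activity
    covariates with an optional estimated temperature change-point that
    switches a coefficient, fit by adaptive random-walk Metropolis MCMC,
    with DIC, R-squared, Gelman-Rubin diagnostics and nested model
    selection.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
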