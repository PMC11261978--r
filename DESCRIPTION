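Package: chemolimit
Title: Information Rates and the Physical Limit of Bacterial Chemosensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how much behaviorally-relevant information a
    chemotaxing bacterium encodes about its chemical environment, and how
    close that encoding comes to the physical limit set by stochastic
    ligand-molecule arrivals at its receptors. Implements exact
    linear-Gaussian (Kalman-Bucy) filtering of two observation channels --
    diffusive molecule arrivals and CheA kinase activity -- to compute
    posterior variances, squared correlations, and predictive information
    rates for the run-and-tumble signal s(t) = g*vx(t); closed-form
    small-signal expressions and dimensionless signal-to-noise ratios;
    agent-based run-and-tumble, molecule-arrival and kinase simulations;
    and the parameter-inference procedures (velocity autocorrelation fits,
    step-response fits, Ornstein-Uhlenbeck noise fits via marginal
    likelihood, MWC gain fits, robust population summaries) together with
    seeded synthetic-data generators that emulate the underlying
    single-cell tracking and FRET experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
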