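Package: stochShield
Title: Stochastic Shielding and Edge Importance for First-Order Markov
    Reaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact per-edge decomposition of the stationary variance of an
    observable defined on a first-order Markov reaction network (edge
    importance), per-edge power spectral densities and lagged covariances,
    and stochastic-shielding simulation: Gillespie stochastic simulation and
    Langevin (multivariate Ornstein-Uhlenbeck) paths in which the noise on
    selected edges is suppressed while retained edges share common random
    numbers. Includes closed-form reversal diagnostics for 3-state chains
    (the hidden-edge importance fraction eta, its factorization and upper
    bounds), builders for the Colquhoun-Hawkes 5-state nicotinic
    acetylcholine receptor model and a catalogue of 3-state chains, rate
    scans, and lognormal rate ensembles with inversion statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
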