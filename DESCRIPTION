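Package: seedbankHMM
Title: Hidden Markov Modelling of Weed Seed-Bank Dynamics from Abundance-Class Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates annual-weed life-history traits (germination and establishment
    rate, seed survival in the soil seed bank, per-plant seed production) separately
    for each crop management action from time series of semi-quantitative emerged-plant
    abundance classes, using a hidden Markov model whose hidden state is the censored
    seed-bank abundance class. Transition kernels are obtained either by Monte-Carlo
    simulation of the count-level binomial dynamics or by exact enumeration; parameters
    are estimated by maximum likelihood (controlled random search) or by
    Metropolis-within-Gibbs posterior sampling under uniform priors. Estimated traits
    are combined into a Leslie matrix to derive asymptotic growth rates and damping
    ratios per management action. Includes a calibrated synthetic survey generator,
    one-step-ahead class prediction, and the cross-validation efficiency metrics used
    to assess predictive quality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
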