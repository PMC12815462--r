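Package: eidt
Title: Individuality Transfer Across Decision-Making Task Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers an individual's decision-making tendencies from a source
    task condition to a target condition via an encoder / individual latent
    representation / decoder / task solver (EIDT) pipeline. An encoder GRU maps
    a person's choice sequences to a low-dimensional individual latent
    representation; a linear hypernetwork decoder generates the weights of a
    small GRU task solver that predicts the same person's choices in a
    different task condition. Includes a multi-step Markov decision task
    simulator with drifting transition probabilities, Q-learning cognitive
    model simulation and maximum-likelihood fitting (the baselines), an
    evidence-accumulation variant for single-shot perceptual decisions with
    response-time binning, synthetic agent-population generators, and
    evaluation tools (trial-wise negative log-likelihood, behavior-match rate,
    cross-individual latent-distance Gamma regression, on-policy comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
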