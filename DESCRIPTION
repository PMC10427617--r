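Package: pedex
Title: Evolution of Skilled Foot Use in Birds: Scoring, Detection, and
    Ancestral State Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of pedal manipulation
    (skilled foot use) in birds from citizen-science media records.
    Aggregates per-media behavioral scores into species-level dexterity
    indices, estimates clade-specific media-count detection thresholds
    from logistic detection curves, summarizes tree samples into maximum
    clade credibility trees, prunes and grafts taxa, fits discrete-trait
    continuous-time Markov models (equal-rates, symmetric, all-rates-
    different, and a hidden precursor-state model) by maximum likelihood
    with AIC comparison, reconstructs marginal ancestral states and counts
    independent gains and losses, performs phylogenetic generalized least
    squares and Brownian-motion ancestral reconstruction of continuous
    characters, and simulates complete synthetic studies with full ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    ape,
    Matrix,
    jsonlite,
    phytools,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
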