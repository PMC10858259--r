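Package: stylevol
Title: Macroevolution of Style-Length Polymorphism on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the macroevolution of rare binary floral
    characters, motivated by style-length polymorphism (heterostyly and
    related stylar conditions) across the angiosperms. Implements
    continuous-time Markov (Mk) models of discrete character evolution with
    optional hidden rate categories, maximum-likelihood fitting via
    Felsenstein's pruning algorithm with AIC model selection, marginal
    ancestral-state reconstruction, exact endpoint-conditioned stochastic
    character mapping by uniformization (counts and ages of trait gains and
    losses, lineages-through-time by state), Pagel-style tests of correlated
    evolution between two binary traits (eight-model battery of dependent
    versus independent evolution), deterministic binary coding of floral and
    pollination traits, and forward simulators of trees and trait histories
    for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phangorn,
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
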