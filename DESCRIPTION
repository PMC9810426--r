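Package: cultree
Title: Bayesian Inference of Cultural Trait Transmission on Population Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spread of discrete cultural traits over a
    network of populations and for Bayesian inference of the underlying
    transmission and mutation processes. Each generation every population
    copies the state of a (possibly different) population according to a
    row-stochastic transmission matrix and then mutates it according to a
    row-stochastic mutation matrix. The package provides forward simulation
    of the dynamics, a latent transmission-history representation whose
    backward lineage tracing yields a single-trait genealogy, likelihood
    computation on that genealogy by Felsenstein's pruning algorithm, and two
    Metropolis-Hastings samplers: an exact sampler over the full history
    matrix, and a heuristic sampler that replaces the history prior with a
    pool of genealogies drawn by backward coalescent simulation. Posterior
    summaries include per-population state probabilities, maximum clade
    credibility trees, and spatial maps; results are returned as tibbles and
    trees interoperate with 'ape'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
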