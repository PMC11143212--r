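Package: evograph
Title: Evolutionary Dynamics of New Mutations on Complex Population Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fixation of new mutations in populations
    structured as undirected graphs. Implements Birth-death and death-Birth
    Moran process simulation on arbitrary connected graphs, an exact
    absorbing-Markov-chain solver for small graphs, degree-class diffusion
    approximations for fixation probability with closed-form amplification
    factors (alpha_dB, alpha_Bd), a regular-perturbation solver for strongly
    assortative structures, graph family generators, a degree-preserving
    simulated-annealing rewirer that tunes degree assortativity, and a
    spatial-network pipeline that turns cell coordinate tables (for example,
    stem cell niche locations in bone marrow) into geometric graphs and scans
    them for suppression of selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
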