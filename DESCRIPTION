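Package: pggnet
Title: Evolution of Cooperation in Public Goods Games on Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weak-selection theory and simulation tools for the evolution of
    cooperation in multiplayer public goods games on arbitrary unweighted
    networks. Computes the critical synergy factor above which natural
    selection favours the fixation of cooperators, under pairwise-comparison,
    death-birth and birth-death update rules with average or accumulated
    payoffs, from the coalescence times of ancestral random walks. Also
    computes critical benefit-to-cost ratios for pairwise donation games,
    enumerates all connected graphs up to eight nodes and classifies them by
    their cooperation thresholds, validates the theory against an exact
    Markov-chain computation of fixation probabilities on small graphs, and
    runs agent-based Monte Carlo simulations of strategy evolution with a
    compiled inner loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
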