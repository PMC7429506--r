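Package: netweave
Title: Motif-Based Alignment and Seasonal Dynamics of Bipartite Ecological
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyse time series of weekly weighted bipartite ecological
    networks (e.g. plant-pollinator communities). Species are characterised
    by motif-based structural roles (positions within all connected
    guild-labelled bipartite motifs of 3-5 species), networks are aligned by
    a stochastic optimisation that pairs species with similar roles, and the
    repeated alignments are compiled into an alignment matrix from which
    recurring groups of species positions are detected by short-random-walk
    community detection. Species movement among position groups over a
    season, including network entry and exit, is modelled with a Bayesian
    time-dependent multinomial logistic regression fitted by adaptive MCMC,
    with WAIC-based model comparison. A synthetic-data generator with known
    ground truth (phenologies, planted position groups, transition dynamics)
    supports testing and calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
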