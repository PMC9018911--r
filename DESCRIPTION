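Package: commCouple
Title: Communication Models of Structure-Function Coupling in Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives a battery of forty communication-model predictor matrices
    (flow graphs, navigation, communicability, path transitivity, matching
    index, shortest path length, cosine similarity, search information, mean
    first passage time, and Euclidean distance) from sparse structural
    connectivity, and regresses functional connectivity on them globally, per
    region, and in multi-predictor models. Includes spatially constrained
    (spin) permutation nulls with system-level enrichment tests, continuous
    core-periphery decomposition of predictor pair-count graphs by simulated
    annealing, consensus modularity clustering of regional predictor
    preferences, lifespan age-trend statistics with nuisance residualization,
    and a synthetic connectome cohort generator with planted, recoverable
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
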