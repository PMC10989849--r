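Package: bioticnet
Title: Quantifying Community-Level Biotic Associations in Microbial Networks
Version: 0.1.0
Authors@R: person("bioticnet", "developers", email = "bioticnet@example.org",
    role = c("aut", "cre"))
Description: Infers signed co-occurrence networks from microbial abundance
    tables, strips out edges explainable by dispersal limitation or
    environmental selection using per-edge Mantel link tests against
    geographic and environmental distance matrices, collapses the remaining
    putative biotic associations to per-taxon connectedness and per-sample
    community-level positive/negative association strengths, and relates
    those strengths to alpha and beta diversity via forward-selection
    ordinary least squares and Mantel tests. Includes a random-matrix-theory
    threshold scan for choosing the correlation cut-off and a synthetic
    community generator with planted environmentally driven, spatially
    driven, and biotic taxon pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
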