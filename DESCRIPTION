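Package: shnet
Title: Species-Habitat Network Analysis for Heterogeneous Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of species-habitat networks built from site-by-species
    abundance matrices with habitat labels. Computes per-site diversity
    (richness and the Smith-Wilson Evar evenness), bipartite network
    architecture metrics (connectance, weighted NODF nestedness, Barber
    bipartite modularity with a stochastic label-propagation optimizer,
    robustness to ordered species extinctions) with fixed-margin Patefield
    null-model z-scores, a unipartite patch projection with Opsahl weighted
    degree centrality, community detection (multilevel, walktrap, spinglass),
    mixing parameter and partition agreement, and habitat-effect linear
    models with Tukey HSD compact letter displays. Includes a synthetic
    landscape generator with planted modular or nested structure so the full
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
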