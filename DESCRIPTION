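Package: micronetstab
Title: Stability Analysis of Soil Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for profiling soil amplicon (ASV) count
    tables: rarefaction and alpha/beta diversity with a permutation-based
    PERMANOVA, signed co-occurrence network inference by thresholded
    Spearman correlation with Benjamini-Hochberg control, network topology
    metrics (degree, density, clustering, path length, Louvain modularity),
    community cohesion and the negative-to-positive cohesion stability
    ratio, robustness under random and targeted node removal, efficiency
    based vulnerability, and partial least squares path modelling linking
    treatment, soil properties, community structure and crop performance.
    Includes a synthetic-community generator with planted correlation
    modules and a known path model so every stage has a recoverable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    vegan,
    picante,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
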