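Package: pitmudr
Title: Microbial Biogeography and Community Assembly Analysis for Fermentation Pit Mud
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for spatiotemporal microbial community surveys of
    Baijiu fermentation pit mud and similar engineered anaerobic habitats.
    Starting from an OTU count table, a rooted phylogeny, taxonomy and sample
    metadata, the package computes alpha diversity with age-trend regression,
    Bray-Curtis and weighted UniFrac beta diversity with NMDS and PERMANOVA,
    phylogenetic null-model inference of community assembly (betaMNTD / betaNTI
    with the stochastic / homogeneous-selection / heterogeneous-selection
    partition), Spearman co-occurrence networks with topology, robustness and
    vulnerability summaries, and age-biomarker discovery by random-forest
    cross-validated feature selection and an LDA effect-size (LEfSe-style)
    procedure. A seeded synthetic-data generator produces phylogenies,
    metadata and overdispersed count tables with known ground truth
    (assembly regime, succession, planted biomarkers, correlation blocks)
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    picante,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
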