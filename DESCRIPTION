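Package: twobead
Title: Coarse-Grained Two-Bead Protein Models for Sequence Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained two-bead (Calpha/Cbeta) representation of
    protein structure together with a physics-based multi-term scoring
    function and a knowledge-based contact potential for protein folding
    and binding. Provides Random-Energy-Model decoy generators and robust
    Z-score specificity measures, Metropolis-Hastings parameterization of
    term weights, sequence-space sampling of the fold-score landscape, a
    forward population-genetic simulator with truncation selection on
    folding stability and ligand binding, and post-simulation analytics
    (Pamilo-Bianchi-Li dN/dS, site classification, hydrophobicity
    partitioning, and rate-heterogeneity model comparison). Synthetic
    structure generators make the full stack testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
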