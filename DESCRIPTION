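Package: tbpnoise
Title: Promoter Microstate Dynamics and TBP-Driven Gene Expression Noise
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discrete-time Markov-chain simulation of TATA-box binding
    protein (TBP) microstates at a yeast promoter (free promoter, monomeric
    TBP, Mot1p-, SAGA- and TFIID-bound assemblies) and the downstream
    analysis stages that connect promoter identity to cell-to-cell gene
    expression noise: TATA-box/TATA-like site classification from sequence,
    median-split co-activator regulation classes from ChIP occupancy,
    protein-binding microarray (PBM) signal aggregation, coefficient of
    variation and distance-from-median (DM) noise metrics, and a
    flow-cytometry processing chain with scatter gating and size correction.
    Synthetic-data generators emulate each input so the full pipeline is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
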