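Package: qsmine
Title: Mining Quorum-Sensing Genes and Building Microbial Communication Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining quorum-sensing (QS) synthases and receptors
    from microbial proteomes and for constructing and comparing three
    community-level networks: the bipartite species-by-QS-language
    communication network, the Spearman co-occurrence network with a
    random-matrix-theory (generalized Brody distribution) threshold, and
    the metabolite-interchange network. Includes seed-entry cataloguing
    with longest-sequence deduplication and keyword screens, homology
    expansion by local protein alignment with Karlin-Altschul E-value
    gating, amino-acid-composition classifier screening with
    cross-validation and Friedman/Nemenyi classifier selection,
    Poisson-corrected distances with Neighbor-Joining trees, core-community
    identification, and a synthetic-data generator that plants known
    homologs, co-occurring OTU blocks and metabolite overlaps so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
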