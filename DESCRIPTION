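Package: pindexr
Title: Subgenome Divergence and Polyploidy Classification from Gene
    Retention Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies divergence between the subgenomes of a
    paleopolyploid genome from windowed gene-retention differences
    measured against an outgroup reference genome (the polyploidy index,
    or P-index), and classifies polyploidy events as allo- or
    autopolyploid. Includes readers for gene position tables (GFF3, BED,
    TSV) and collinearity files (MCScanX-style and plain anchor TSV), a
    greedy partitioner that tiles collinear blocks into subgenome tracks,
    windowed retention profiling, the P-index in pairwise,
    multi-subgenome, self-reference and recursive-event modes, pairwise
    subgenome distance matrices with grouping, a gene-loss simulator that
    deletes genes in geometric-length runs under balanced or unbalanced
    scenarios, and synthetic end-to-end fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
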