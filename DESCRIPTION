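Package: cldatlas
Title: Comparative Genomics of Chlorite Dismutase Genomic Neighborhoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for using chlorite dismutase (Cld) as a genomic biomarker
    for oxidized chlorine species. Identifies Cld proteins in a family
    alignment by the four catalytic key residues, partitions protein trees
    into clades by mean branch distance, extracts the +/- 10 gene
    neighborhood around each cld gene, clusters neighborhood proteins into
    subfamilies, ranks subfamily linkage to cld with a co-occurrence-network
    clustering coefficient, groups neighborhoods by subfamily content with
    dimensionality reduction and density clustering, screens genomes for
    (per)chlorate-reductase co-presence, and converts biomarker gene
    frequencies into estimated fractions of genomes. A synthetic-data
    generator plants known anchors, subfamilies, archetypes and residue
    mutations so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    GenomicRanges,
    Rtsne,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
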