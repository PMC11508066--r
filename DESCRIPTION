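Package: focalvar
Title: Breed-Specific Variant Classification and Length-Bias-Free Enrichment
    from Multi-Genome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies variants private to a focal genome from pairwise
    difference tables against a panel of comparison genomes, annotates their
    coding effects (synonymous, missense, splice-site), tests genes, Gene
    Ontology categories, gene +/- 10 kb windows and genomic regions for an
    excess of focal-private mutations with an exact binomial tail test that is
    free of gene-length bias, detects long focal-only genomic regions from
    coverage masks, and profiles their tandem-repeat and G-quadruplex content.
    Includes a fully synthetic breed-panel simulator with machine-readable
    ground truth so the whole pipeline is testable without external genome
    assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
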