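Package: nemacomp
Title: Comparative Phylogenomics of Nematode Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogenomic analysis of nematode genomes:
    single-copy orthologue selection and paralogue screening of gene trees,
    quartet-score supertree estimation, equal-rates Mk ancestral state
    reconstruction by stochastic character mapping, phylogenetic generalized
    least squares of genome size against genome-content features under
    Brownian motion, assembly and gene-structure metrics (N50, intron span,
    intergenic distance, orthologue log2 ratios), and gene-family
    duplication and substitution-rate analysis. A synthetic-data module
    generates every input class with known ground truth so the whole
    pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    yaml,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
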