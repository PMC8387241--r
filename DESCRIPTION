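Package: syncomstats
Title: Strain-Level Analysis of Synthetic Root Microbiota Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gnotobiotic synthetic-community (SynCom) experiments
    on plant roots: simulation of paired two-host strain panels and
    Dirichlet-multinomial community count tables under competition and
    sequential-inoculation designs, strain-level quantification of 16S
    amplicon reads by perfect-match assignment against in-silico extracted
    reference amplicons, cross-referencing of sequence-indexed culture
    collections with community profiles (recoverable OTUs and recovery
    rates), community ecology statistics (Shannon diversity, Bray-Curtis
    PCoA, PERMANOVA, Kruskal-Wallis with Dunn post hoc, qPCR bacterial
    load), and per-strain host-preference and invasiveness indices with
    false-discovery-rate controlled significance testing, index
    correlation, and family-removal robustness analysis.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    permute,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'community.R'
    'design.R'
    'io.R'
    'irl.R'
    'panel.R'
    'plots.R'
    'preference.R'
    'quant.R'
    'reads.R'
    'simulate.R'
    'syncomstats-package.R'
    'tidiers.R'
    'utils.R'
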