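Package: dnvnet
Title: De Novo Variant Calling, Enrichment and Brain Co-Expression
    Network Analysis for Trio Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for trio exome studies of de novo
    variants (DNVs) in neurodevelopmental disorders. Calls DNVs from trio
    genotype tables under explicit genotype- and site-level quality filters
    (genotype quality, depth, allele balance, site quality, mapping quality,
    strand bias, call rate, exact Hardy-Weinberg test), aggregates seven
    in-silico pathogenicity predictors into a damaging call, fits a Poisson
    model to per-trio DNV counts, tests gene sets by random-sampling
    empirical p-values of the form (s+1)/(t+1) and by exact hypergeometric
    tails, builds Spearman co-expression networks of case genes across brain
    region by developmental-stage strata and tests their interconnectedness
    against control-gene networks, and integrates evidence lines into a
    per-gene ranking. Ships a synthetic-data generator that emulates every
    input (trio VCF + pedigree, predictor annotations, gene scores and
    reference lists, BrainSpan-style expression) with planted truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
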