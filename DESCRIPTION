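Package: occumeta
Title: Occupancy Modeling for Functional Presence-Absence in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adapts macroecological occupancy modeling to metagenomic
    surveys of functional capacity. Independent marker genes of an enzyme
    complex (e.g. McrABG for methanogenesis, PmoABC for aerobic
    methanotrophy) are treated as replicate surveys of a single metagenome,
    so that a non-detection can be decomposed into the probability that the
    function is genuinely absent versus missed by sequencing and assembly.
    Provides marker-sequence curation (length windows, labeled top-hit
    classification, tree-based long-branch screening), detection-history
    construction under several site-aggregation schemes, maximum-likelihood
    single-species and two-species (multivariate Bernoulli) occupancy models
    with logit-linked covariates, AIC model comparison, conditional
    co-occurrence prediction, and a seeded synthetic-data generator for
    parameter-recovery experiments.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
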