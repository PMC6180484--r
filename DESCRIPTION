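Package: orphanfit
Title: Assigning Genes to Orphan Metabolic Reactions from Genome-Wide
    Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide analysis of knock-down/knock-out fitness
    screens (TnSeq-style gene-by-condition fitness matrices and per-insertion
    tables) and for using them to propose candidate genes for orphan reactions
    in genome-scale metabolic models.  Implements boolean gene-protein-reaction
    (GPR) rule parsing to disjunctive normal form, max-min collapse of gene
    fitness or expression profiles to reaction profiles, shared-metabolite
    reaction neighborhoods with greedy currency-metabolite pruning, the
    Association Likelihood Score (mean Spearman correlation to the two
    most-correlated non-orphan neighbor reactions), promoter-adjusted and
    expression-combined scores, empirical Bayesian and unbiased assignment
    confidences, uniform null baselines, and leave-one-out top-k validation.
    Also provides companion genome statistics: non-coding region fitness,
    binomial region-effect tests, co-fitness/co-expression class enrichment,
    minimum-hypergeometric (mHG/mmHG) ranked-list statistics, and PSSM-based
    promoter scanning, plus a seed-deterministic synthetic screen generator
    for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
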