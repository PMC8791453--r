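Package: stageSMG
Title: Stage-Stratified Detection of Significantly Mutated Genes in
    Endometrioid Endometrial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stage-stratified analysis of somatic mutation
    cohorts in endometrioid endometrial carcinoma (EEC): MAF-dialect
    ingestion and TCGA-style variant filtering, an NHGRI-style
    multi-caller consensus filter (read support, germline VAF, dbSNP,
    caller agreement), a binomial background/signal model for
    significantly mutated gene (SMG) detection with statistical power
    analysis, Benjamini-Hochberg FDR with restricted-hypothesis
    re-testing to classify late-stage-specific SMGs, characterization of
    microsatellite-instability target genes (homopolymer-tract indels,
    protein-change recurrence, subgroup enrichment by Fisher's exact
    test, missense impact consensus), and a seeded synthetic-cohort
    generator with a ground-truth ledger for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
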