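# stageSMG

Stage-stratified detection of significantly mutated genes (SMGs) in
endometrioid endometrial carcinoma (EEC), for cancer genomicists asking
whether a driver catalog differs between late-stage (FIGO III/IV) and
early-stage (I/II) disease. The package covers the full path from somatic
mutation tables to stage-specific driver calls: MAF-dialect ingestion and
TCGA MC3-style filtering, an NHGRI-style multi-caller consensus filter, a
binomial background/signal SMG model with exact power analysis,
Benjamini–Hochberg FDR with restricted-hypothesis re-testing, and
characterization of microsatellite-instability (MSI) target genes
(homopolymer-tract indels, recurrence, subgroup enrichment, missense
impact consensus). A seeded synthetic-cohort generator with a
ground-truth ledger makes every stage testable without downloads.

## The model

A gene's mutated-tumor count is treated as binomial. Under the background,
a tumor carries a non-silent mutation in the gene with probability

    p0 = 1 - (1 - mu * f_g)^((3/4) * L)

(`mu`: background rate per base per tumor; `f_g`: gene-specific rate
factor, default 3.9; `L`: gene length, default 1500 bp; `(3/4) L`
approximates the non-silent positions). A driver mutated in a fraction
`r` of tumors with mis-detection `m` gives `p1 = p0 + r (1 - m)`. The
per-gene p-value is the one-sided upper tail `P(X >= x)` under
`Bin(n, p0)`; detection power at per-test level `alpha/k` is an exact
binomial tail sum under `p1`. SMGs are genes with Benjamini–Hochberg
q-value <= 0.10. Late-stage SMGs are then re-tested in the early-stage
cohort with q-values adjusted for the *late-stage SMG count* (k = 14 in
the published analysis); a gene whose early-stage q stays above 0.10 is
classified late-stage-specific.

## Worked example

Classify the published 14 late-stage SMGs from their early-stage
p-values, adjusting for 14 tests:

```r
library(stageSMG)

late14 <- union_smgs(list(nhgri = nhgri_late_smgs()$gene,
                          tcga  = tcga_late_smgs()$gene))
length(late14$genes)        # 14 unique late-stage SMGs across both cohorts

tab <- restricted_retest(late14$genes, early_stage_pvalues(),
                         q_threshold = 0.10)
tab$gene[tab$stage_specific]
```

This prints:

```
[1] 14
[1] "PAX6" "KLF3"
```

i.e. 12 of the 14 late-stage SMGs are already significantly mutated in
early-stage tumors; only *PAX6* (early q = 0.139) and *KLF3*
(early q = 0.999) are late-stage-specific. The subgroup enrichment of the
two genes reproduces from the published counts:

```r
fisher_2x2(11, 130, 1, 194)$p_value   # PAX6: MSI 11/141 vs CN 1/195
#> [1] 0.0004271296
```

An end-to-end synthetic run (simulate, filter, scan, re-test):

```r
gen <- generate_cohort(cohort_config(
  drivers = driver_spec("PAX6", r_early = 0.035, r_late = 0.259,
                        subgroup = "MSI_hypermutated",
                        indel_homopolymer_fraction = 0.8,
                        hotspots = "P375Hfs*7"),
  seed = 2024))
cohort <- gen$cohort
cohort$variants <- exclude_noncoding(filter_tcga_variants(cohort$variants))
mu_hat <- estimate_background_mu(cohort, n_genes = 300, gene_params = gen$genes)
res <- run_stage_analysis(cohort, background_model(mu_hat),
                          n_genes = 300, gene_params = gen$genes)
res$stage_table
```

The numbered scripts under `analysis/` run this workflow at full scale
(simulation, both filtering dialects, late-stage scan, stage-specificity,
power curves, MSI-target reports) and write their tables under
`results/`. On the default seed the synthetic PAX6-like driver comes out
late-stage-specific with an early-stage p of 0.123 (the published value
is 0.129), and the recurrence/homopolymer reports recover the planted
hotspot frameshifts inside their (C)7-style tracts.

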