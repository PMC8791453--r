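#!/usr/bin/env Rscript
# Stage-specificity classification by restricted-hypothesis BH re-testing.
#  (a) The published path: the 14 late-stage SMGs' early-stage p-values are
#      re-adjusted for exactly 14 tests; genes whose early-stage q-value
#      stays above 0.10 are late-stage-specific.
#  (b) The synthetic end-to-end path: late SMGs from the binomial scan are
#      re-tested against early-stage p-values from the same engine, with
#      Q-Q diagnostics of the early-stage p-values.

suppressPackageStartupMessages(library(stageSMG))

fix_dir <- "results/synthetic_cohort"
out_dir <- "results/stage_specificity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## (a) published early-stage p-values ---------------------------------------
late14 <- union_smgs(list(nhgri = nhgri_late_smgs()$gene,
                          tcga = tcga_late_smgs()$gene))$genes
tab <- restricted_retest(late14, early_stage_pvalues(), q_threshold = 0.10)
readr::write_tsv(tab, file.path(out_dir, "published_stage_specificity.tsv"))
cat(sprintf("published path: %d of %d late SMGs early-significant; stage-specific: %s\n",
            sum(!tab$stage_specific), nrow(tab),
            paste(tab$gene[tab$stage_specific], collapse = ", ")))

## (b) synthetic end-to-end path --------------------------------------------
meta <- yaml::read_yaml(file.path(fix_dir, "meta.yaml"))
variants <- read_maf(file.path(fix_dir, "maf.tsv"), dialect = "generic")
clinical <- read_clinical(file.path(fix_dir, "clinical.tsv"))
kept <- exclude_noncoding(filter_tcga_variants(variants))
cohort <- new_cohort(kept, clinical, name = "synthetic")

gene_params <- readr::read_tsv(file.path(fix_dir, "genes.tsv"),
                               show_col_types = FALSE)
mu_hat <- estimate_background_mu(cohort, n_genes = meta$n_genes,
                                 gene_params = gene_params)
res <- run_stage_analysis(cohort, background_model(mu = mu_hat),
                          n_genes = meta$n_genes, gene_params = gene_params)
readr::write_tsv(res$stage_table, file.path(out_dir, "synthetic_stage_specificity.tsv"))
readr::write_tsv(res$qq, file.path(out_dir, "synthetic_early_qq.tsv"))
cat(sprintf("synthetic path: late SMGs %s\n",
            paste(res$late_smgs$gene, collapse = ", ")))
print(as.data.frame(res$stage_table), digits = 3)
cat("note: with 27 MSI-hypermutated late-stage tumors, recovery of a driver\n")
cat("mutated in 26% of them is power-limited, and an early-stage frequency\n")
cat("of 11.4% (KLF3-like) is detectable at n = 270 while 3.5% (PAX6-like)\n")
cat("is not -- see the power curves from analysis/05_power_analysis.R.\n")
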