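#!/usr/bin/env Rscript
# Late-stage SMG detection.
#  (a) The published late-stage SMG sets: union of the 6 NHGRI-cohort SMGs
#      and the 12 TCGA-cohort SMGs (Venn-style overlap counts).
#  (b) Binomial-model SMG scan of the synthetic late-stage stratum, BH
#      adjustment over the gene universe, SMG calls at q <= 0.10.

suppressPackageStartupMessages(library(stageSMG))

fix_dir <- "results/synthetic_cohort"
out_dir <- "results/smg_scan"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## (a) published SMG sets ---------------------------------------------------
u <- union_smgs(list(nhgri = nhgri_late_smgs()$gene,
                     tcga = tcga_late_smgs()$gene))
jsonlite::write_json(
  list(genes = u$genes, sizes = as.list(u$sizes),
       overlap = u$overlaps$overlap[1], shared = u$overlaps$shared[[1]]),
  file.path(out_dir, "late_smg_union.json"), auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("published SMG union: %d unique genes; %d shared between cohorts (%s)\n",
            length(u$genes), u$overlaps$overlap[1],
            paste(u$overlaps$shared[[1]], collapse = ", ")))

## (b) synthetic late-stage scan --------------------------------------------
meta <- yaml::read_yaml(file.path(fix_dir, "meta.yaml"))
variants <- read_maf(file.path(fix_dir, "maf.tsv"), dialect = "generic")
clinical <- read_clinical(file.path(fix_dir, "clinical.tsv"))
kept <- exclude_noncoding(filter_tcga_variants(variants))
cohort <- new_cohort(kept, clinical, name = "synthetic")

late <- stratify(cohort, by = "stage_class")$late
# gene-specific background (per-gene length and rate factor); cohort-level
# mu estimated from the late-stage data itself
gene_params <- readr::read_tsv(file.path(fix_dir, "genes.tsv"),
                               show_col_types = FALSE)
mu_hat <- estimate_background_mu(late, n_genes = meta$n_genes,
                                 gene_params = gene_params)
model <- background_model(mu = mu_hat)
cat(sprintf("estimated late-stage background mu: %.3g\n", mu_hat))

results <- smg_scan(late, model, gene_params = gene_params) |>
  adjust_gene_results(n_tests = meta$n_genes)
smgs <- call_smgs(results)
readr::write_tsv(results, file.path(out_dir, "late_gene_results.tsv"))
readr::write_tsv(smgs, file.path(out_dir, "late_smgs.tsv"))
cat(sprintf("late-stage scan: %d genes tested, %d SMGs at q <= 0.10: %s\n",
            nrow(results), nrow(smgs), paste(smgs$gene, collapse = ", ")))
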