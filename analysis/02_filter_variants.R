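#!/usr/bin/env Rscript
# Apply both variant filtering paths to synthetic cohorts and summarize the
# resulting mutation burden.
#  (a) TCGA MC3-style: FILTER designation + MuTect SNVs / Indelocator indels,
#      then noncoding-class exclusion, on the fixture from 01_simulate_cohort.
#  (b) NHGRI-style consensus: read support (>=14 tumor / >=8 normal reads),
#      germline VAF (> 3% excluded), dbSNP (SNP MAF > 5%; any indel),
#      4-caller SNV consensus / 2-caller indel union, on a 15-exome
#      late-stage cohort generated in the NHGRI caller dialect.

suppressPackageStartupMessages(library(stageSMG))

fix_dir <- "results/synthetic_cohort"
out_dir <- "results/filtering"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(fix_dir, "maf.tsv"))) {
  stop("run analysis/01_simulate_cohort.R first")
}

## (a) TCGA-style path -----------------------------------------------------
variants <- read_maf(file.path(fix_dir, "maf.tsv"), dialect = "generic")
clinical <- read_clinical(file.path(fix_dir, "clinical.tsv"))

kept <- filter_tcga_variants(variants)
kept <- exclude_noncoding(kept)
write_maf(kept, file.path(out_dir, "tcga_filtered.tsv"), dialect = "generic")

cohort <- new_cohort(kept, clinical, name = "synthetic-tcga")
burden <- summarize_burden(cohort)
readr::write_tsv(burden$per_sample, file.path(out_dir, "tcga_burden.tsv"))
cat(sprintf("TCGA path: %d -> %d variants; %.1f non-silent per tumor (range %d-%d), %d genes\n",
            nrow(variants), nrow(kept), burden$mean,
            burden$range[1], burden$range[2], burden$n_genes))

## (b) NHGRI-style consensus path ------------------------------------------
nhgri_cfg <- cohort_config(
  cells = tibble::tibble(stage_class = "late",
                         subgroup = "MSI_hypermutated", n = 15L),
  mu = c(MSI_hypermutated = 2e-5),
  n_genes = 300, caller_style = "nhgri",
  depth_violation_rate = 0.04, germline_vaf_rate = 0.03,
  dbsnp_contamination_rate = 0.05, dbsnp_decoy_rate = 0.02,
  caller_dropout_rate = 0.05, noncoding_rate = 0.25,
  seed = 1503L)
nhgri <- generate_cohort(nhgri_cfg)

res <- run_consensus_pipeline(nhgri$cohort$variants, lookup = nhgri$dbsnp)
readr::write_tsv(res$report, file.path(out_dir, "nhgri_filter_report.tsv"))
write_maf(res$variants, file.path(out_dir, "nhgri_filtered.tsv"))

nhgri_burden <- summarize_burden(new_cohort(res$variants,
                                            nhgri$cohort$clinical,
                                            name = "synthetic-nhgri"))
readr::write_tsv(nhgri_burden$per_sample, file.path(out_dir, "nhgri_burden.tsv"))
cat(sprintf("NHGRI path: %d -> %d variants; per-rule drops: %s\n",
            res$n_input, res$n_retained,
            paste(sprintf("%s=%d", res$report$rule, res$report$dropped),
                  collapse = " ")))
cat(sprintf("NHGRI burden: %.1f non-silent per tumor (range %d-%d)\n",
            nhgri_burden$mean, nhgri_burden$range[1], nhgri_burden$range[2]))
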