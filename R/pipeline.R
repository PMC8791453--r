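#' Stage-stratified SMG analysis
#'
#' Orchestrates the core stage comparison on a cohort: split early/late by
#' FIGO stage class, scan the late-stage cohort for SMGs under the
#' binomial background model, call SMGs at the q-value threshold, then
#' re-test exactly those genes in the early-stage cohort with q-values
#' adjusted for the late-stage SMG count. A gene significant late but not
#' early is classified stage-specific.
#'
#' @param cohort An `eec_cohort` with coding/splice variants.
#' @param model A [background_model()].
#' @param n_genes BH family size for the late-stage scan (the gene
#'   universe over which mutations could have been observed); defaults to
#'   the number of mutated genes.
#' @param q_threshold Inclusive SMG q-value threshold.
#' @param early_p Optional external early-stage p-values (named vector or
#'   tibble with `gene`, `p_value`), e.g. from another SMG engine; when
#'   `NULL` they are computed by [smg_scan()] on the early stratum.
#' @param gene_params Optional gene-specific `f_g`/`L` table passed to
#'   [smg_scan()].
#' @return List with `late_results`, `late_smgs`, `stage_table`,
#'   `early_results` (`NULL` under external p-values), `qq` (Q-Q points of
#'   the early-stage p-values), and `counts` (per-stage record counts).
#' @export
run_stage_analysis <- function(cohort, model, n_genes = NULL,
                               q_threshold = 0.10, early_p = NULL,
                               gene_params = NULL) {
  strata <- stratify(cohort, by = "stage_class")
  if (is.null(strata$late)) stop("cohort has no late-stage samples", call. = FALSE)
  late_results <- smg_scan(strata$late, model, gene_params = gene_params) |>
    adjust_gene_results(n_tests = n_genes, q_threshold = q_threshold)
  late_smgs <- call_smgs(late_results, q_threshold)
  if (nrow(late_smgs) == 0) {
    stop("no late-stage SMGs at q <= ", q_threshold, call. = FALSE)
  }

  early_results <- NULL
  if (is.null(early_p)) {
    if (is.null(strata$early)) stop("cohort has no early-stage samples", call. = FALSE)
    early_results <- smg_scan(strata$early, model, gene_params = gene_params)
    early_p <- stats::setNames(early_results$p_value, early_results$gene)
  } else if (is.data.frame(early_p)) {
    early_p <- stats::setNames(early_p$p_value, early_p$gene)
  }
  stage_table <- restricted_retest(late_smgs, early_p,
                                   q_threshold = q_threshold,
                                   missing_p = "one")
  list(
    late_results = late_results,
    late_smgs = late_smgs,
    stage_table = stage_table,
    early_results = early_results,
    qq = qq_points(unname(early_p)),
    counts = c(
      n_samples = nrow(cohort$clinical),
      n_late = if (is.null(strata$late)) 0L else nrow(strata$late$clinical),
      n_early = if (is.null(strata$early)) 0L else nrow(strata$early$clinical),
      n_late_smgs = nrow(late_smgs)
    )
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis and write a report bundle
#'
#' End-to-end flow over a (typically synthetic) cohort: ingest, noncoding
#' exclusion, stage stratification, late-stage SMG scan with BH calling,
#' restricted early-stage re-test, MSI-target characterization of selected
#' genes (per-stratum frequencies, subgroup enrichment by two-tailed
#' Fisher test, homopolymer-tract calls, protein-change recurrence), and a
#' detection power grid. Writes TSV/JSON reports plus a manifest with
#' record counts and md5 checksums of every output file.
#'
#' @param cohort An `eec_cohort` (raw; noncoding classes allowed).
#' @param model A [background_model()].
#' @param out_dir Output directory.
#' @param n_genes BH family size for the SMG scan.
#' @param q_threshold SMG q-value threshold.
#' @param early_p Optional external early-stage p-values (bypass the
#'   internal scan; see [run_stage_analysis()]).
#' @param msi_genes Genes to characterize as candidate MSI targets.
#' @param mu_grid,r_grid Power grid axes.
#' @param min_tract_length Homopolymer tract floor.
#' @return The manifest, invisibly.
#' @export
run_full <- function(cohort, model, out_dir, n_genes = NULL,
                     q_threshold = 0.10, early_p = NULL,
                     msi_genes = character(0),
                     mu_grid = 10^seq(-7, -5, length.out = 25),
                     r_grid = c(0.05, 0.10, 0.20),
                     min_tract_length = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_raw <- nrow(cohort$variants)
  cohort$variants <- exclude_noncoding(cohort$variants, verbose = FALSE)

  stage <- run_stage_analysis(cohort, model, n_genes = n_genes,
                              q_threshold = q_threshold, early_p = early_p)
  readr::write_tsv(stage$late_results, file.path(out_dir, "late_gene_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(stage$late_smgs, file.path(out_dir, "late_smgs.tsv"),
                   progress = FALSE)
  readr::write_tsv(stage$stage_table, file.path(out_dir, "stage_specificity.tsv"),
                   progress = FALSE)
  readr::write_tsv(stage$qq, file.path(out_dir, "qq_points.tsv"),
                   progress = FALSE)

  if (length(msi_genes) > 0) {
    freq <- frequency_table(cohort, msi_genes, by = "subgroup")
    readr::write_tsv(freq, file.path(out_dir, "msi_frequency.tsv"),
                     progress = FALSE)
    v <- cohort$variants
    sel <- v[v$gene %in% msi_genes & !is.na(v$protein_change), , drop = FALSE]
    rec <- recurrence_table(sel)
    readr::write_tsv(rec, file.path(out_dir, "msi_recurrence.tsv"),
                     progress = FALSE)
    indels <- v[v$gene %in% msi_genes & v$variant_type != "SNP", , drop = FALSE]
    if (nrow(indels) > 0) {
      hp <- detect_homopolymers(indels, min_tract_length)
      readr::write_tsv(hp[, c("sample_id", "gene", "pos", "ref_allele",
                              "alt_allele", "protein_change", "tract_base",
                              "tract_length", "in_tract", "callable")],
                       file.path(out_dir, "msi_homopolymer.tsv"),
                       progress = FALSE)
    }
  }

  pg <- power_grid(stage$counts[["n_early"]], model, mu_grid, r_grid)
  readr::write_tsv(tibble::as_tibble(as.data.frame(pg)),
                   file.path(out_dir, "power_grid.tsv"), progress = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    counts = c(n_input_variants = n_raw,
               n_coding_variants = nrow(cohort$variants),
               as.list(stage$counts)),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
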