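new_filter_result <- function(variants, report) {
  list(variants = variants, report = report)
}

report_row <- function(rule, dropped) {
  tibble::tibble(rule = rule, dropped = as.integer(dropped))
}

#' Read a dbSNP-like lookup TSV
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `maf`; a blank `maf` means the
#' population minor allele frequency is unknown. Lookup is keyed by exact
#' allele match (position-only matching would over-exclude multi-allelic
#' sites).
#'
#' @param path Path to the lookup TSV.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @export
read_dbsnp <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    maf = readr::col_double()
  ), progress = FALSE)
  if (any(!is.na(out$maf) & (out$maf < 0 | out$maf > 1))) {
    stop("dbSNP MAF outside [0, 1]", call. = FALSE)
  }
  out
}

dbsnp_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Read-support filter
#'
#' Retains variants with at least `min_tumor_depth` reads covering the
#' site in the tumor and `min_normal_depth` in the matched normal
#' (thresholds inclusive). Variants with missing depths are dropped and
#' tallied under `missing_data`.
#'
#' @param variants Variant tibble.
#' @param min_tumor_depth,min_normal_depth Inclusive minimum read depths.
#' @return List with `variants` (retained) and `report` (per-rule drop
#'   counts).
#' @export
apply_read_support <- function(variants, min_tumor_depth = 14,
                               min_normal_depth = 8) {
  missing <- is.na(variants$t_depth) | is.na(variants$n_depth)
  ok <- !missing & variants$t_depth >= min_tumor_depth &
    variants$n_depth >= min_normal_depth
  report <- dplyr::bind_rows(
    report_row("read_support", sum(!ok & !missing)),
    report_row("read_support_missing_data", sum(missing))
  )
  new_filter_result(variants[ok, , drop = FALSE], report)
}

#' Germline variant-allele-frequency filter
#'
#' Excludes potential germline variants: those with a VAF strictly greater
#' than `max_normal_vaf` in the matched normal (a VAF of exactly the
#' threshold passes). Variants with missing or zero normal depth are
#' dropped under `missing_data`.
#'
#' @param variants Variant tibble.
#' @param max_normal_vaf Maximum tolerated normal VAF (fraction).
#' @return List with `variants` and `report`.
#' @export
apply_germline_vaf <- function(variants, max_normal_vaf = 0.03) {
  missing <- is.na(variants$n_alt_count) | is.na(variants$n_depth) |
    variants$n_depth == 0
  vaf <- ifelse(missing, NA_real_, variants$n_alt_count / variants$n_depth)
  ok <- !missing & vaf <= max_normal_vaf
  report <- dplyr::bind_rows(
    report_row("germline_vaf", sum(!ok & !missing)),
    report_row("germline_vaf_missing_data", sum(missing))
  )
  new_filter_result(variants[ok, , drop = FALSE], report)
}

#' dbSNP-based exclusion
#'
#' SNPs found in the lookup with a population minor allele frequency
#' strictly above `max_maf` are excluded; SNPs present with unknown MAF
#' are retained. Indels present in the lookup are excluded without further
#' evaluation of MAF.
#'
#' @param variants Variant tibble.
#' @param lookup dbSNP lookup tibble (see [read_dbsnp()]).
#' @param max_maf Maximum tolerated SNP population MAF (fraction).
#' @return List with `variants` and `report`.
#' @export
apply_dbsnp <- function(variants, lookup, max_maf = 0.05) {
  key <- dbsnp_key(variants$chrom, variants$pos, variants$ref_allele,
                   variants$alt_allele)
  lk <- dbsnp_key(lookup$chrom, lookup$pos, lookup$ref, lookup$alt)
  idx <- match(key, lk)
  present <- !is.na(idx)
  maf <- lookup$maf[idx]
  is_snp <- variants$variant_type == "SNP"
  drop <- present & ifelse(is_snp, !is.na(maf) & maf > max_maf, TRUE)
  report <- report_row("dbsnp", sum(drop))
  new_filter_result(variants[!drop, , drop = FALSE], report)
}

#' Multi-caller consensus filter
#'
#' SNVs must be called by every algorithm in `snv_required` (default: all
#' of Strelka, Shimmer, SomaticSniper, MuTect); indels by at least one of
#' `indel_any_of` (default: Strelka or Shimmer). Variants with an empty
#' caller set are dropped.
#'
#' @param variants Variant tibble.
#' @param snv_required Callers all of which must support an SNV.
#' @param indel_any_of Callers any of which suffices for an indel.
#' @param caller_sep Delimiter within the callers column.
#' @return List with `variants` and `report`.
#' @export
apply_caller_consensus <- function(variants,
                                   snv_required = c("Strelka", "Shimmer",
                                                    "SomaticSniper", "MuTect"),
                                   indel_any_of = c("Strelka", "Shimmer"),
                                   caller_sep = "|") {
  sets <- split_callers(variants$callers, caller_sep)
  is_snp <- variants$variant_type == "SNP"
  ok <- vapply(seq_along(sets), function(i) {
    cs <- sets[[i]]
    if (length(cs) == 0) return(FALSE)
    if (is_snp[i]) all(snv_required %in% cs) else any(indel_any_of %in% cs)
  }, logical(1))
  new_filter_result(variants[ok, , drop = FALSE],
                    report_row("caller_consensus", sum(!ok)))
}

#' Run the full high-confidence consensus filtering pipeline
#'
#' Applies, in order: read support, germline VAF, dbSNP exclusion,
#' multi-caller consensus, and noncoding-class exclusion. Each dropped
#' variant is attributed to the first failing rule, so the report counts
#' reconcile exactly with the input size.
#'
#' @param variants Variant tibble.
#' @param lookup dbSNP lookup tibble, or `NULL` to skip the dbSNP rule.
#' @param min_tumor_depth,min_normal_depth,max_normal_vaf,max_snp_maf,snv_required,indel_any_of,caller_sep
#'   Rule parameters, passed to the individual filters.
#' @param verbose Log per-rule counts.
#' @return List with `variants` (retained), `report` (tibble of per-rule
#'   drop counts), `n_input`, `n_retained`.
#' @export
run_consensus_pipeline <- function(variants, lookup = NULL,
                                   min_tumor_depth = 14, min_normal_depth = 8,
                                   max_normal_vaf = 0.03, max_snp_maf = 0.05,
                                   snv_required = c("Strelka", "Shimmer",
                                                    "SomaticSniper", "MuTect"),
                                   indel_any_of = c("Strelka", "Shimmer"),
                                   caller_sep = "|", verbose = TRUE) {
  n_input <- nrow(variants)
  steps <- list()

  r <- apply_read_support(variants, min_tumor_depth, min_normal_depth)
  steps[[1]] <- r$report
  r <- apply_germline_vaf(r$variants, max_normal_vaf)
  steps[[2]] <- r$report
  if (!is.null(lookup)) {
    r <- apply_dbsnp(r$variants, lookup, max_snp_maf)
    steps[[3]] <- r$report
  }
  r <- apply_caller_consensus(r$variants, snv_required, indel_any_of, caller_sep)
  steps[[length(steps) + 1]] <- r$report
  kept <- exclude_noncoding(r$variants, verbose = FALSE)
  steps[[length(steps) + 1]] <- report_row("noncoding",
                                           nrow(r$variants) - nrow(kept))

  report <- dplyr::bind_rows(steps)
  if (verbose) {
    message(sprintf("consensus pipeline: %d in, %d retained (%s)",
                    n_input, nrow(kept),
                    paste(sprintf("%s: %d", report$rule, report$dropped),
                          collapse = ", ")))
  }
  stopifnot(nrow(kept) + sum(report$dropped) == n_input)
  list(variants = kept, report = report,
       n_input = n_input, n_retained = nrow(kept))
}
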