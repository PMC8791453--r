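#' @importFrom rlang .data
NULL

variant_columns <- c(
  "sample_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
  "variant_type", "variant_classification", "filter_status", "callers",
  "t_depth", "t_alt_count", "n_depth", "n_alt_count",
  "protein_change", "context_seq", "context_offset"
)

mandatory_variant_columns <- c(
  "sample_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
  "variant_type", "variant_classification"
)

maf_dialect_map <- function(dialect) {
  path <- system.file("extdata", "maf_dialects.yaml", package = "stageSMG")
  maps <- yaml::read_yaml(path)$dialects
  if (!dialect %in% names(maps)) {
    stop("unknown MAF dialect: ", dialect, " (known: ",
         paste(names(maps), collapse = ", "), ")", call. = FALSE)
  }
  unlist(maps[[dialect]])
}

#' Read a MAF-dialect somatic mutation table
#'
#' Reads a tab-delimited mutation annotation format (MAF) file, mapping
#' dialect-specific column names (TCGA MC3, NHGRI in-house, or the
#' package's generic schema) onto the internal variant schema. Rows whose
#' mandatory fields cannot be parsed, whose classification token is not in
#' the controlled vocabulary, or that violate record invariants
#' (`pos >= 1`, alt read count not exceeding depth, SNP iff both alleles
#' are single non-gap bases) are rejected with row-numbered diagnostics.
#' Noncoding classifications are parsed and retained: their removal is a
#' downstream filter ([exclude_noncoding()]), not a parse decision.
#'
#' @param path Path to a tab-delimited MAF file.
#' @param dialect One of `"generic"`, `"tcga_mc3"`, `"nhgri"`.
#' @param caller_sep Delimiter of the caller-provenance column (default
#'   `"|"`, the MC3 CENTERS convention).
#' @param verbose Log parsed/rejected row counts via [message()].
#' @return A tibble of variants (one row per retained record) with a
#'   `"rejected"` attribute: a tibble of `(row, reason)` for rejected rows.
#' @export
read_maf <- function(path, dialect = "generic", caller_sep = "|",
                     verbose = TRUE) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  map <- maf_dialect_map(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0) stop("empty MAF file: ", path, call. = FALSE)
  missing_cols <- setdiff(unname(map[mandatory_variant_columns]), names(raw))
  if (length(missing_cols) > 0) {
    stop("MAF file is missing mandatory column(s) for dialect '", dialect,
         "': ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (internal in variant_columns) {
    src <- map[[internal]]
    out[[internal]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA_character_
  }
  for (col in c("pos", "t_depth", "t_alt_count", "n_depth", "n_alt_count",
                "context_offset")) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }

  reason <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    ifelse(is.na(reason) & bad, why, reason)
  }
  for (col in mandatory_variant_columns) {
    reason <- flag(is.na(out[[col]]), paste0("unparseable ", col))
  }
  reason <- flag(!out$variant_classification %in% maf_classifications(),
                 "unknown variant_classification")
  reason <- flag(!out$variant_type %in% c("SNP", "INS", "DEL"),
                 "unknown variant_type")
  reason <- flag(out$pos < 1, "pos < 1")
  is_base <- function(x) nchar(x) == 1 & x != "-"
  snp_like <- is_base(out$ref_allele) & is_base(out$alt_allele)
  reason <- flag(out$variant_type == "SNP" & !snp_like,
                 "SNP with non-single-base alleles")
  reason <- flag(out$variant_type != "SNP" & snp_like,
                 "single-base substitution not typed as SNP")
  reason <- flag(out$t_alt_count > out$t_depth, "t_alt_count > t_depth")
  reason <- flag(out$n_alt_count > out$n_depth, "n_alt_count > n_depth")

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (verbose) {
    message(sprintf("read_maf: %d rows parsed, %d rejected (%s)",
                    nrow(out) - nrow(rejected), nrow(rejected), basename(path)))
    if (nrow(rejected) > 0) {
      shown <- utils::head(rejected, 5)
      message(paste(sprintf("  row %d: %s", shown$row, shown$reason),
                    collapse = "\n"))
    }
  }
  out <- out[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Write a variant table as a MAF-dialect TSV
#'
#' @param variants Variant tibble (internal schema).
#' @param path Output path.
#' @param dialect Dialect whose column names to emit.
#' @export
write_maf <- function(variants, path, dialect = "generic") {
  map <- maf_dialect_map(dialect)
  out <- variants[, variant_columns[variant_columns %in% names(variants)]]
  names(out) <- unname(map[names(out)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical annotation TSV
#'
#' Expects a header with `sample_id`, `stage`, `grade`, `subgroup`.
#' FIGO stages I/II are classed early, III/IV late; anything else is
#' `"unknown"` and is routed to an unknown stratum that downstream
#' analyses skip.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with `sample_id`, `figo_stage`, `stage_class`,
#'   `grade`, `subgroup`.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "stage", "grade", "subgroup")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("clinical TSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  make_clinical(raw$sample_id, raw$stage, raw$grade, raw$subgroup)
}

make_clinical <- function(sample_id, figo_stage, grade, subgroup) {
  figo_stage <- ifelse(figo_stage %in% c("I", "II", "III", "IV"),
                       figo_stage, "unknown")
  grade <- ifelse(grade %in% c("G1", "G2", "G3"), grade, "unknown")
  known_sub <- c("MSI_hypermutated", "CN_low", "CN_high", "POLE_ultramutated")
  subgroup <- ifelse(subgroup %in% known_sub, subgroup, "unassigned")
  tibble::tibble(
    sample_id = sample_id,
    figo_stage = figo_stage,
    stage_class = stage_class_of(figo_stage),
    grade = grade,
    subgroup = subgroup
  )
}

#' Derive early/late stage class from FIGO stage
#'
#' Early-stage disease is FIGO stage I or II (uterus-confined); late-stage
#' is III or IV.
#'
#' @param figo_stage Character vector of FIGO stages.
#' @return Character vector over `{"early", "late", "unknown"}`.
#' @export
stage_class_of <- function(figo_stage) {
  dplyr::case_when(
    figo_stage %in% c("I", "II") ~ "early",
    figo_stage %in% c("III", "IV") ~ "late",
    TRUE ~ "unknown"
  )
}

#' Bundle variants and clinical records into a cohort
#'
#' Validates that every variant's sample appears in the clinical table and
#' that clinical sample ids are unique.
#'
#' @param variants Variant tibble.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param name Cohort label used in reports.
#' @return An object of class `eec_cohort`.
#' @export
new_cohort <- function(variants, clinical, name = "cohort") {
  if (anyDuplicated(clinical$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  orphans <- setdiff(unique(variants$sample_id), clinical$sample_id)
  if (length(orphans) > 0) {
    stop("variants reference samples absent from clinical table: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(variants = variants, clinical = clinical, name = name),
            class = "eec_cohort")
}

#' @export
print.eec_cohort <- function(x, ...) {
  cat(sprintf("<eec_cohort '%s'>: %d samples, %d variants\n",
              x$name, nrow(x$clinical), nrow(x$variants)))
  invisible(x)
}

split_callers <- function(callers, caller_sep = "|") {
  strsplit(ifelse(is.na(callers), "", callers), caller_sep, fixed = TRUE)
}

has_caller <- function(callers, caller, caller_sep = "|") {
  vapply(split_callers(callers, caller_sep), function(cs) caller %in% cs,
         logical(1))
}

#' TCGA MC3-style variant retention filter
#'
#' Retains variants whose FILTER designation is in `keep_filters` (default
#' PASS, WGA, Native_WGA_mix) and whose caller provenance includes the
#' designated SNV caller for SNPs (default MuTect) or the designated indel
#' caller for insertions/deletions (default Indelocator). Output is a
#' subset of the input with order preserved; the operation is idempotent.
#'
#' @param variants Variant tibble.
#' @param keep_filters FILTER tokens to retain.
#' @param snv_caller,indel_caller Required caller per variant type.
#' @param caller_sep Delimiter within the callers column.
#' @param verbose Log input/output counts.
#' @return Filtered variant tibble.
#' @export
filter_tcga_variants <- function(variants,
                                 keep_filters = c("PASS", "WGA", "Native_WGA_mix"),
                                 snv_caller = "MUTECT",
                                 indel_caller = "INDELOCATOR",
                                 caller_sep = "|",
                                 verbose = TRUE) {
  keep <- variants$filter_status %in% keep_filters
  is_snp <- variants$variant_type == "SNP"
  keep <- keep & ifelse(is_snp,
                        has_caller(variants$callers, snv_caller, caller_sep),
                        has_caller(variants$callers, indel_caller, caller_sep))
  if (verbose) {
    message(sprintf("filter_tcga_variants: %d in, %d retained",
                    nrow(variants), sum(keep)))
  }
  variants[keep, , drop = FALSE]
}

#' Remove noncoding variant classes
#'
#' Drops UTR, flank, intronic, RNA/lincRNA and de-novo-start calls,
#' retaining coding classes, `Splice_Site`, and `Silent`.
#'
#' @inheritParams filter_tcga_variants
#' @return Filtered variant tibble (subset of input, order preserved).
#' @export
exclude_noncoding <- function(variants, verbose = TRUE) {
  keep <- !variants$variant_classification %in% noncoding_classifications()
  if (verbose) {
    message(sprintf("exclude_noncoding: %d in, %d retained",
                    nrow(variants), sum(keep)))
  }
  variants[keep, , drop = FALSE]
}

#' Stratify a cohort by stage class and/or molecular subgroup
#'
#' Each sample (with its variants) is assigned to exactly one stratum.
#' Samples whose value in any stratifier is unknown/unassigned go to an
#' `"unknown"` stratum, which downstream analyses skip.
#'
#' @param cohort An `eec_cohort`.
#' @param by Character vector among `"stage_class"`, `"subgroup"`.
#' @return Named list of `eec_cohort` objects.
#' @export
stratify <- function(cohort, by = "stage_class") {
  stopifnot(inherits(cohort, "eec_cohort"))
  by <- match.arg(by, c("stage_class", "subgroup"), several.ok = TRUE)
  cl <- cohort$clinical
  unknown_tokens <- c("unknown", "unassigned")
  vals <- lapply(by, function(b) cl[[b]])
  is_unknown <- Reduce(`|`, lapply(vals, function(v) v %in% unknown_tokens))
  label <- do.call(paste, c(vals, sep = "."))
  label[is_unknown] <- "unknown"
  out <- lapply(split(cl$sample_id, label), function(ids) {
    new_cohort(cohort$variants[cohort$variants$sample_id %in% ids, , drop = FALSE],
               cl[cl$sample_id %in% ids, , drop = FALSE],
               name = cohort$name)
  })
  for (lab in names(out)) out[[lab]]$name <- paste0(cohort$name, ":", lab)
  out
}

#' Summarize per-sample non-silent mutation burden
#'
#' Variants must already be restricted to coding/splice classes. Samples
#' with zero non-silent variants count in the denominator of the mean.
#'
#' @param cohort An `eec_cohort`.
#' @return List with `per_sample` (tibble of `sample_id`, `n_nonsilent`),
#'   `total`, `mean`, `range` (min, max), `n_genes` (distinct genes with a
#'   non-silent variant), `n_samples`.
#' @export
summarize_burden <- function(cohort) {
  stopifnot(inherits(cohort, "eec_cohort"))
  n_samples <- nrow(cohort$clinical)
  if (n_samples == 0) stop("cohort has no samples", call. = FALSE)
  v <- cohort$variants
  ns <- v[is_nonsilent(v$variant_classification), , drop = FALSE]
  counts <- table(factor(ns$sample_id, levels = cohort$clinical$sample_id))
  per_sample <- tibble::tibble(sample_id = names(counts),
                               n_nonsilent = as.integer(counts))
  list(
    per_sample = per_sample,
    total = nrow(ns),
    mean = nrow(ns) / n_samples,
    range = c(min(per_sample$n_nonsilent), max(per_sample$n_nonsilent)),
    n_genes = dplyr::n_distinct(ns$gene),
    n_samples = n_samples
  )
}
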