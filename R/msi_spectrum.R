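revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Homopolymer-tract call for a single indel
#'
#' Decides whether an insertion or deletion edits a homopolymer tract: a
#' run of a single nucleotide (e.g. a (C)7 tract), the classic substrate
#' for replication slippage in mismatch-repair-deficient tumors. The
#' flanking context is supplied as a window string with a declared 0-based
#' offset of the edited position: for a deletion, the index of the first
#' deleted base within the window; for an insertion, the index of the base
#' after which the new bases sit.
#'
#' For a deletion the tract is the maximal run of identical bases
#' containing the deleted base(s); `in_tract` additionally requires all
#' deleted bases to equal the run base. For an insertion the tract is the
#' run of the inserted base immediately flanking the insertion point on
#' either side (the two sides adjoin across the insertion point);
#' `in_tract` requires all inserted bases to be identical. Dinucleotide
#' and higher-order repeats never qualify: only mononucleotide runs count.
#'
#' @param variant_type `"INS"` or `"DEL"` (`"SNP"` is a contract
#'   violation).
#' @param ref_allele,alt_allele MAF-convention alleles (`"-"` for the gap
#'   side of an indel).
#' @param context_seq Window string; `NA` yields an uncallable result.
#' @param context_offset 0-based offset of the edited position.
#' @param min_tract_length Minimum run length to call a tract (default 5,
#'   a conventional instability floor).
#' @return List with `tract_base`, `tract_length`, `in_tract`, `window`,
#'   `callable`.
#' @export
detect_homopolymer <- function(variant_type, ref_allele, alt_allele,
                               context_seq, context_offset,
                               min_tract_length = 5) {
  if (variant_type == "SNP") {
    stop("detect_homopolymer() applies to indels only", call. = FALSE)
  }
  uncallable <- list(tract_base = NA_character_, tract_length = NA_integer_,
                     in_tract = NA, window = NA_character_, callable = FALSE)
  if (is.na(context_seq) || is.na(context_offset)) return(uncallable)
  chars <- strsplit(context_seq, "")[[1]]
  n <- length(chars)

  run_around <- function(i, base) {
    # maximal run of `base` through position i (1-based), 0 if mismatch
    if (i < 1 || i > n || chars[i] != base) return(0L)
    l <- i
    while (l > 1 && chars[l - 1] == base) l <- l - 1
    r <- i
    while (r < n && chars[r + 1] == base) r <- r + 1
    as.integer(r - l + 1)
  }

  if (variant_type == "DEL") {
    del <- strsplit(ref_allele, "")[[1]]
    first <- context_offset + 1
    if (first < 1 || context_offset + length(del) > n) return(uncallable)
    if (!identical(chars[first:(context_offset + length(del))], del)) {
      warning("context window does not contain the deleted bases; uncallable")
      return(uncallable)
    }
    base <- del[1]
    len <- run_around(first, base)
    in_tract <- len >= min_tract_length && all(del == base)
  } else {
    ins <- strsplit(alt_allele, "")[[1]]
    base <- ins[1]
    left_i <- context_offset + 1          # base just before the insertion
    right_i <- context_offset + 2         # base just after
    if (left_i < 0 || right_i > n + 1) return(uncallable)
    left <- if (left_i >= 1 && left_i <= n && chars[left_i] == base) {
      l <- left_i
      while (l > 1 && chars[l - 1] == base) l <- l - 1
      left_i - l + 1L
    } else 0L
    right <- if (right_i >= 1 && right_i <= n && chars[right_i] == base) {
      r <- right_i
      while (r < n && chars[r + 1] == base) r <- r + 1
      r - right_i + 1L
    } else 0L
    len <- left + right
    in_tract <- len >= min_tract_length && all(ins == base)
  }
  list(tract_base = base, tract_length = as.integer(len),
       in_tract = in_tract, window = context_seq, callable = TRUE)
}

#' Homopolymer-tract calls for a table of indels
#'
#' Row-wise wrapper around [detect_homopolymer()] for the indel rows of a
#' variant table; SNP rows are not allowed.
#'
#' @param variants Variant tibble restricted to `variant_type` INS/DEL.
#' @param min_tract_length Minimum qualifying run length.
#' @return `variants` with `tract_base`, `tract_length`, `in_tract`,
#'   `callable` columns appended.
#' @export
detect_homopolymers <- function(variants, min_tract_length = 5) {
  if (any(variants$variant_type == "SNP")) {
    stop("detect_homopolymers() applies to indels only", call. = FALSE)
  }
  calls <- lapply(seq_len(nrow(variants)), function(i) {
    detect_homopolymer(variants$variant_type[i], variants$ref_allele[i],
                       variants$alt_allele[i], variants$context_seq[i],
                       variants$context_offset[i], min_tract_length)
  })
  variants$tract_base <- vapply(calls, `[[`, character(1), "tract_base")
  variants$tract_length <- vapply(calls, `[[`, integer(1), "tract_length")
  variants$in_tract <- vapply(calls, `[[`, logical(1), "in_tract")
  variants$callable <- vapply(calls, `[[`, logical(1), "callable")
  variants
}

#' Protein-change recurrence table
#'
#' Counts, per (gene, protein change), the number of distinct samples
#' carrying that change (a sample contributes once however many times the
#' change appears in it) and flags changes seen in at least `min_samples`
#' samples as recurrent.
#'
#' @param variants Variant tibble with `protein_change` populated for the
#'   variants to count (rows with `NA` are ignored).
#' @param min_samples Recurrence threshold (default 2).
#' @return Tibble with `gene`, `protein_change`, `n_samples`, `recurrent`.
#' @export
recurrence_table <- function(variants, min_samples = 2) {
  v <- variants[!is.na(variants$protein_change), , drop = FALSE]
  out <- dplyr::distinct(v, .data$gene, .data$protein_change, .data$sample_id) |>
    dplyr::count(.data$gene, .data$protein_change, name = "n_samples")
  out$recurrent <- out$n_samples >= min_samples
  dplyr::arrange(out, dplyr::desc(.data$n_samples), .data$gene,
                 .data$protein_change)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-tailed p-value for the table `[[a, b], [c, d]]` by summing
#' hypergeometric point probabilities not exceeding that of the observed
#' table (the dominant two-tailed convention), with a `1 + 1e-7` relative
#' tolerance on the comparison; arithmetic in log space.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1: a, b; row 2:
#'   c, d).
#' @return List with `table` (2x2 matrix), `odds_ratio` (`a*d / (b*c)`,
#'   `Inf` when `b*c = 0` with `a*d > 0`), and `p_value`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero table", call. = FALSE)
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  logp <- stats::dhyper(support, m1, m2, k, log = TRUE)
  obs <- stats::dhyper(a, m1, m2, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(table = matrix(counts, 2, 2, byrow = TRUE),
       odds_ratio = odds, p_value = min(1, p))
}

#' Per-stratum mutation frequency table for selected genes
#'
#' For each gene and each stratum of the cohort (plus an `"all"` row), a
#' sample counts as mutated iff it carries at least one non-silent variant
#' in that gene. Percentages are reported to one decimal.
#'
#' @param cohort An `eec_cohort` with coding/splice variants.
#' @param genes Character vector of gene symbols.
#' @param by Stratifiers among `"stage_class"`, `"subgroup"` (see
#'   [stratify()]).
#' @return Tibble with `gene`, `stratum`, `n_mutated`, `n_total`,
#'   `percent`.
#' @export
frequency_table <- function(cohort, genes, by = c("stage_class", "subgroup")) {
  stopifnot(inherits(cohort, "eec_cohort"))
  absent <- setdiff(genes, unique(cohort$variants$gene))
  if (length(absent) > 0) {
    warning("gene(s) never mutated in cohort: ", paste(absent, collapse = ", "))
  }
  strata <- c(list(all = cohort), stratify(cohort, by = by))
  rows <- lapply(names(strata), function(lab) {
    co <- strata[[lab]]
    v <- co$variants
    ns <- v[is_nonsilent(v$variant_classification), , drop = FALSE]
    n_total <- nrow(co$clinical)
    dplyr::bind_rows(lapply(genes, function(g) {
      n_mut <- dplyr::n_distinct(ns$sample_id[ns$gene == g])
      tibble::tibble(gene = g, stratum = lab, n_mutated = n_mut,
                     n_total = n_total,
                     percent = round(100 * n_mut / max(1, n_total), 1))
    }))
  })
  dplyr::bind_rows(rows)
}

predictor_impact_tokens <- c(
  MutationAssessor = "high",
  PROVEAN = "deleterious",
  SIFT = "damaging",
  PolyPhen2 = "probably-damaging"
)

#' Missense functional-impact consensus
#'
#' Aggregates labels from up to four in-silico predictors. A missense
#' variant is called impactful when at least 3 of the 4 predictors report
#' their impact token: "high" (MutationAssessor), "deleterious" (PROVEAN),
#' "damaging" (SIFT), "probably-damaging" (PolyPhen2). Missing predictors
#' count as non-impact.
#'
#' @param labels Named character vector/list; names must be among
#'   `MutationAssessor`, `PROVEAN`, `SIFT`, `PolyPhen2`.
#' @return List with `labels`, `n_impact`, `impact`.
#' @export
missense_consensus <- function(labels) {
  labels <- unlist(labels)
  unknown <- setdiff(names(labels), names(predictor_impact_tokens))
  if (length(unknown) > 0 || (length(labels) > 0 && is.null(names(labels)))) {
    stop("unknown predictor(s): ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  hits <- !is.na(labels) &
    labels == predictor_impact_tokens[names(labels)]
  n_impact <- sum(hits)
  list(labels = labels, n_impact = as.integer(n_impact),
       impact = n_impact >= 3)
}
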