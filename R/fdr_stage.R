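#' Benjamini-Hochberg step-up q-values
#'
#' Step-up procedure: sort p-values ascending, compute
#' `raw_i = p_(i) * n_tests / i`, then `q_(i) = min_{j >= i} raw_j`,
#' capped at 1. `n_tests` may exceed the number of supplied p-values (the
#' restricted-hypothesis setting: q-values for a pre-specified gene set
#' adjusted for the size of that set, or for a larger family in which the
#' remaining tests are uninformative). Tied p-values share an identical
#' q-value; results are returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param n_tests Number of tests to adjust for; defaults to `length(p)`,
#'   must be at least `length(p)`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p, n_tests = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  if (n_tests < length(p)) {
    stop("n_tests must be at least length(p)", call. = FALSE)
  }
  if (length(p) == 0) return(numeric(0))
  o <- order(p)
  raw <- p[o] * n_tests / seq_along(p)
  q <- pmin(1, rev(cummin(rev(raw))))
  out <- numeric(length(p))
  out[o] <- q
  out
}

#' Fill q-values and SMG flags on gene test results
#'
#' @param results Tibble from [smg_scan()].
#' @param n_tests BH family size; defaults to the number of tested genes.
#'   Pass the full gene universe size when unmutated genes (implicit
#'   p = 1) belong to the family.
#' @param q_threshold SMG q-value threshold (inclusive).
#' @return `results` with `q_value` and `is_smg` filled.
#' @export
adjust_gene_results <- function(results, n_tests = NULL, q_threshold = 0.10) {
  n_tests <- if (is.null(n_tests)) nrow(results) else max(n_tests, nrow(results))
  results$q_value <- bh_adjust(results$p_value, n_tests)
  results$is_smg <- results$q_value <= q_threshold
  results
}

#' Call significantly mutated genes at a q-value threshold
#'
#' Genes with `q_value <= q_threshold` (inclusive boundary), sorted by
#' ascending p-value with the gene symbol as a stable tie-break.
#'
#' @param results Tibble with `gene`, `p_value`, `q_value` (filled).
#' @param q_threshold Inclusive q-value threshold.
#' @return Tibble of SMGs (`gene`, `p_value`, `q_value`).
#' @export
call_smgs <- function(results, q_threshold = 0.10) {
  if (any(is.na(results$q_value))) {
    stop("q_value not filled; run adjust_gene_results() first", call. = FALSE)
  }
  out <- results[results$q_value <= q_threshold,
                 intersect(c("gene", "p_value", "q_value"), names(results)),
                 drop = FALSE]
  dplyr::arrange(out, .data$p_value, .data$gene)
}

#' Restricted-hypothesis early-stage re-test
#'
#' Given the set of late-stage SMGs and per-gene p-values from the
#' early-stage cohort, recomputes q-values over exactly those genes with
#' `n_tests` equal to the late-stage SMG count, and classifies a gene as
#' stage-specific when its early-stage q-value exceeds the threshold
#' (i.e., the gene fails to reach significance in early-stage disease).
#'
#' @param late_smgs Character vector of late-stage SMG gene symbols (or a
#'   tibble with columns `gene` and optionally `q_value`, e.g. from
#'   [call_smgs()]).
#' @param early_p Named numeric vector of early-stage p-values, or a
#'   tibble with `gene` and `p_value`.
#' @param q_threshold Inclusive q-value significance threshold.
#' @param missing_p `"error"` to fail when a late SMG has no early-stage
#'   p-value; `"one"` to fall back to p = 1 (a gene never mutated in the
#'   early cohort carries no evidence of early significance).
#' @return Tibble with `gene`, `late_q` (if supplied), `early_p`,
#'   `early_q`, `stage_specific`, sorted by `early_p`.
#' @export
restricted_retest <- function(late_smgs, early_p, q_threshold = 0.10,
                              missing_p = c("error", "one")) {
  missing_p <- match.arg(missing_p)
  late_q <- NULL
  if (is.data.frame(late_smgs)) {
    if ("q_value" %in% names(late_smgs)) late_q <- late_smgs$q_value
    late_smgs <- late_smgs$gene
  }
  if (anyDuplicated(late_smgs)) stop("duplicate genes in SMG set", call. = FALSE)
  if (is.data.frame(early_p)) {
    early_p <- stats::setNames(early_p$p_value, early_p$gene)
  }
  p <- unname(early_p[late_smgs])
  if (anyNA(p)) {
    absent <- late_smgs[is.na(p)]
    if (missing_p == "error") {
      stop("no early-stage p-value for: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    p[is.na(p)] <- 1
  }
  q <- bh_adjust(p, n_tests = length(late_smgs))
  out <- tibble::tibble(
    gene = late_smgs,
    early_p = p,
    early_q = q,
    stage_specific = q > q_threshold
  )
  if (!is.null(late_q)) out <- tibble::add_column(out, late_q = late_q,
                                                  .after = "gene")
  dplyr::arrange(out, .data$early_p, .data$gene)
}

#' Union of SMG sets across cohorts
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return List with `genes` (sorted unique union), `sizes` (per input
#'   set), and `overlaps` (tibble of pairwise intersection counts, for
#'   Venn rendering).
#' @export
union_smgs <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  overlaps <- dplyr::bind_rows(lapply(pairs, function(pr) {
    tibble::tibble(set1 = pr[1], set2 = pr[2],
                   overlap = length(intersect(sets[[pr[1]]], sets[[pr[2]]])),
                   shared = list(sort(intersect(sets[[pr[1]]], sets[[pr[2]]]))))
  }))
  list(genes = sort(unique(unlist(sets))),
       sizes = vapply(sets, length, integer(1)),
       overlaps = overlaps)
}

#' Quantile-quantile points for p-values
#'
#' Observed p-values sorted ascending against uniform quantiles
#' `(i - 0.5) / n`, both on the `-log10` scale. Zero p-values are clamped
#' to `zero_floor` with a warning (they are off the chart, not an error).
#'
#' @param p Numeric vector of p-values.
#' @param zero_floor Replacement for p = 0 before taking logs.
#' @return Tibble with `expected` and `observed` (`-log10` scale).
#' @export
qq_points <- function(p, zero_floor = 1e-300) {
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning(sum(p == 0), " zero p-value(s) clamped to ", zero_floor)
    p[p == 0] <- zero_floor
  }
  n <- length(p)
  # i-th smallest p against the (i - 0.5)/n uniform quantile
  tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
}
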