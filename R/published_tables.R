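#' Published late-stage SMG tables and early-stage p-values
#'
#' Printed inputs from the source study of late- versus early-stage
#' endometrioid endometrial carcinoma (EEC), used to drive the
#' restricted-hypothesis re-testing machinery exactly as the original
#' analysis did (the per-gene p-values there came from MutSigCV v1.4,
#' which this package deliberately does not re-implement).
#'
#' * `nhgri_late_smgs()`: the 6 SMGs (q <= 0.10) from 15 NHGRI late-stage
#'   EEC exomes, with mutated-tumor counts and MutSigCV p/q-values.
#' * `tcga_late_smgs()`: the 12 SMGs from 66 TCGA late-stage EECs.
#' * `early_stage_pvalues()`: early-stage (n = 270) MutSigCV p-values for
#'   the 14 unique late-stage SMGs, plus the q-values as printed (after
#'   adjustment for 14 tests) for cross-checking.
#' * `klf3_pax6_frequencies()`: non-silent KLF3/PAX6 mutation counts by
#'   tumor stage and molecular subgroup in 336 non-ultramutated TCGA EECs.
#' * `nhgri_burden_counts()`: the NHGRI cohort's variant class totals
#'   (nonsynonymous SNVs and indels, splice-site, synonymous) over 15
#'   tumors.
#'
#' @return Tibbles (or a list for `nhgri_burden_counts()`).
#' @name published_tables
NULL

#' @rdname published_tables
#' @export
nhgri_late_smgs <- function() {
  tibble::tribble(
    ~gene,     ~n_mutated, ~n_tumors, ~p_value,  ~q_value,
    "PTEN",    13L,        15L,       2.11e-15,  3.98e-11,
    "ARID1A",  11L,        15L,       1.27e-10,  1.20e-06,
    "RPL22",    4L,        15L,       1.44e-07,  9.07e-04,
    "OR6C75",   4L,        15L,       7.84e-06,  3.70e-02,
    "CTCF",     5L,        15L,       1.26e-05,  4.74e-02,
    "AP1S1",    3L,        15L,       2.13e-05,  6.70e-02
  )
}

#' @rdname published_tables
#' @export
tcga_late_smgs <- function() {
  tibble::tribble(
    ~gene,     ~n_mutated, ~n_tumors, ~p_value,  ~q_value,
    "ARID1A",  29L,        66L,       0,         0,
    "PIK3R1",  21L,        66L,       5.55e-16,  5.24e-12,
    "PTEN",    46L,        66L,       2.00e-15,  1.26e-11,
    "PIK3CA",  25L,        66L,       7.27e-14,  3.43e-10,
    "TP53",    19L,        66L,       3.07e-13,  1.16e-09,
    "KRAS",    18L,        66L,       7.22e-11,  2.27e-07,
    "RPL22",    6L,        66L,       4.89e-08,  1.08e-04,
    "CTCF",    12L,        66L,       4.99e-08,  1.08e-04,
    "CTNNB1",  18L,        66L,       5.16e-08,  1.08e-04,
    "PAX6",     7L,        66L,       1.04e-06,  1.96e-03,
    "RNF43",    9L,        66L,       4.61e-06,  7.91e-03,
    "KLF3",     7L,        66L,       6.34e-06,  9.96e-03
  )
}

#' @rdname published_tables
#' @export
early_stage_pvalues <- function() {
  tibble::tribble(
    ~gene,     ~p_value,  ~q_printed,
    "AP1S1",   0,         0,
    "ARID1A",  0,         0,
    "CTNNB1",  0,         0,
    "PIK3CA",  0,         0,
    "PTEN",    0,         0,
    "RNF43",   0,         0,
    "RPL22",   0,         0,
    "TP53",    1.11e-15,  1.94e-15,
    "CTCF",    2.78e-15,  4.05e-15,
    "PIK3R1",  2.89e-15,  4.05e-15,
    "KRAS",    6.88e-15,  8.76e-15,
    "OR6C75",  1.89e-03,  2.21e-03,
    "PAX6",    1.29e-01,  1.39e-01,
    "KLF3",    9.99e-01,  9.99e-01
  )
}

#' @rdname published_tables
#' @export
klf3_pax6_frequencies <- function() {
  tibble::tribble(
    ~stage,   ~subgroup,          ~gene,   ~n_mutated, ~n_total,
    "all",    "all",              "KLF3",  20L, 336L,
    "all",    "MSI_hypermutated", "KLF3",  20L, 141L,
    "all",    "CN_low",           "KLF3",   0L, 140L,
    "all",    "CN_high",          "KLF3",   0L,  55L,
    "late",   "all",              "KLF3",   7L,  66L,
    "late",   "MSI_hypermutated", "KLF3",   7L,  27L,
    "late",   "CN_low",           "KLF3",   0L,  21L,
    "late",   "CN_high",          "KLF3",   0L,  18L,
    "early",  "all",              "KLF3",  13L, 270L,
    "early",  "MSI_hypermutated", "KLF3",  13L, 114L,
    "early",  "CN_low",           "KLF3",   0L, 119L,
    "early",  "CN_high",          "KLF3",   0L,  37L,
    "all",    "all",              "PAX6",  12L, 336L,
    "all",    "MSI_hypermutated", "PAX6",  11L, 141L,
    "all",    "CN_low",           "PAX6",   1L, 140L,
    "all",    "CN_high",          "PAX6",   0L,  55L,
    "late",   "all",              "PAX6",   7L,  66L,
    "late",   "MSI_hypermutated", "PAX6",   7L,  27L,
    "late",   "CN_low",           "PAX6",   0L,  21L,
    "late",   "CN_high",          "PAX6",   0L,  18L,
    "early",  "all",              "PAX6",   5L, 270L,
    "early",  "MSI_hypermutated", "PAX6",   4L, 114L,
    "early",  "CN_low",           "PAX6",   1L, 119L,
    "early",  "CN_high",          "PAX6",   0L,  37L
  )
}

#' @rdname published_tables
#' @export
nhgri_burden_counts <- function() {
  list(
    n_samples = 15L,
    nonsynonymous_snv = 1405L,
    nonsynonymous_indel = 809L,
    splice_site = 92L,
    synonymous = 573L,
    per_tumor_range = c(9L, 542L)
  )
}
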