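# Fixture constructors and independent oracles used across the suite.

make_variants <- function(n = 1, ...) {
  defaults <- tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    gene = "GENE1",
    chrom = "chr1",
    pos = 1000L + seq_len(n),
    ref_allele = "A",
    alt_allele = "T",
    variant_type = "SNP",
    variant_classification = "Missense_Mutation",
    filter_status = "PASS",
    callers = "Strelka|Shimmer|SomaticSniper|MuTect",
    t_depth = 50L,
    t_alt_count = 10L,
    n_depth = 40L,
    n_alt_count = 0L,
    protein_change = NA_character_,
    context_seq = NA_character_,
    context_offset = NA_integer_
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

make_clin <- function(sample_id, stage = "III", grade = "G2",
                      subgroup = "MSI_hypermutated") {
  tibble::tibble(
    sample_id = sample_id,
    figo_stage = rep_len(stage, length(sample_id)),
    stage_class = stage_class_of(rep_len(stage, length(sample_id))),
    grade = rep_len(grade, length(sample_id)),
    subgroup = rep_len(subgroup, length(sample_id))
  )
}

write_tsv_fixture <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# --- independent oracles -------------------------------------------------

# BH step-up by direct transcription of the definition: raw_i = p_(i)*m/i,
# q_(i) = min over j >= i of raw_j, capped at 1, back in input order.
bh_oracle <- function(p, n_tests = length(p)) {
  o <- order(p)
  ps <- p[o]
  len <- length(p)
  raw <- ps * n_tests / seq_len(len)
  q <- numeric(len)
  for (i in seq_len(len)) q[i] <- min(1, min(raw[i:len]))
  out <- numeric(len)
  out[o] <- q
  out
}

# Upper-tail binomial exceedance by explicit pmf summation.
pvalue_oracle <- function(x, n, p0) {
  if (x == 0) return(1)
  sum(dbinom(x:n, n, p0))
}

# Two-tailed Fisher p by enumeration over the hypergeometric support with
# probabilities from lchoose (no dhyper), same 1 + 1e-7 tie tolerance.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(N, k)
  obs <- lchoose(m1, a) + lchoose(m2, c) - lchoose(N, k)
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# Tolerance for comparing a computed value against a printed value: half a
# unit in the last printed significant digit (3 significant figures).
printed_tol <- function(x, digits = 3) {
  ifelse(x == 0, 0, 0.5 * 10^(floor(log10(abs(x))) - digits + 1) * (1 + 1e-9))
}

expect_matches_printed <- function(computed, printed, digits = 3) {
  expect_true(all(abs(computed - printed) <= printed_tol(printed, digits)),
              label = paste0("computed [", paste(signif(computed, 4), collapse = ", "),
                             "] vs printed [", paste(printed, collapse = ", "), "]"))
}
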