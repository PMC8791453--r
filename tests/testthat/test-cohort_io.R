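test_that("read_maf parses valid rows and keeps noncoding classes", {
  maf <- make_variants(3, variant_classification = c("Missense_Mutation",
                                                     "Intron", "Splice_Site"))
  path <- write_tsv_fixture(maf)
  out <- suppressMessages(read_maf(path, dialect = "generic"))
  expect_equal(nrow(out), 3)
  # noncoding rows are retained at parse time; exclusion is a filter
  expect_true("Intron" %in% out$variant_classification)
  expect_equal(nrow(attr(out, "rejected")), 0)
})

test_that("read_maf rejects invariant-violating rows with diagnostics", {
  maf <- make_variants(4,
    t_alt_count = c(10L, 60L, 10L, 10L),          # row 2: alt > depth
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Weird_Class", "Silent"),  # row 3 unknown
    pos = c(100L, 101L, 102L, 0L))                 # row 4: pos < 1
  path <- write_tsv_fixture(maf)
  out <- suppressMessages(read_maf(path, dialect = "generic"))
  expect_equal(nrow(out), 1)
  rej <- attr(out, "rejected")
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_match(rej$reason[1], "t_alt_count")
  expect_match(rej$reason[2], "classification")
})

test_that("read_maf enforces the SNP/allele-shape invariant", {
  maf <- make_variants(3,
    variant_type = c("SNP", "DEL", "INS"),
    ref_allele = c("AT", "A", "-"),
    alt_allele = c("T", "-", "CG"))
  path <- write_tsv_fixture(maf)
  out <- suppressMessages(read_maf(path, dialect = "generic"))
  expect_equal(out$variant_type, c("DEL", "INS"))
  expect_match(attr(out, "rejected")$reason, "non-single-base")
})

test_that("read_maf errors on missing mandatory columns and empty files", {
  maf <- make_variants(2)
  maf$variant_classification <- NULL
  path <- write_tsv_fixture(maf)
  expect_error(suppressMessages(read_maf(path, dialect = "generic")),
               "variant_classification")
  empty <- write_tsv_fixture(make_variants(0))
  expect_error(suppressMessages(read_maf(empty, dialect = "generic")), "empty")
})

test_that("tcga_mc3 dialect columns round-trip through write_maf/read_maf", {
  v <- make_variants(2, callers = "MUTECT|MUSE", filter_status = "WGA")
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(v, path, dialect = "tcga_mc3")
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_true(all(c("Hugo_Symbol", "Tumor_Sample_Barcode", "FILTER",
                    "CENTERS", "Variant_Classification") %in% header))
  back <- suppressMessages(read_maf(path, dialect = "tcga_mc3"))
  expect_equal(back$gene, v$gene)
  expect_equal(back$callers, v$callers)
})

test_that("filter_tcga_variants applies FILTER and caller rules", {
  v <- make_variants(5,
    variant_type = c("SNP", "SNP", "DEL", "DEL", "SNP"),
    ref_allele = c("A", "A", "A", "A", "A"),
    alt_allele = c("T", "T", "-", "-", "T"),
    filter_status = c("PASS", "nonpreferredpair", "WGA", "PASS", "PASS"),
    callers = c("MUTECT|MUSE", "MUTECT", "VARSCANI", "INDELOCATOR", "MUSE"))
  out <- filter_tcga_variants(v, verbose = FALSE)
  # retained: SNP PASS with MuTect; DEL PASS with Indelocator
  expect_equal(out$sample_id, c("S1", "S4"))
  # idempotent, subset of input
  expect_identical(filter_tcga_variants(out, verbose = FALSE), out)
})

test_that("exclude_noncoding drops exactly the noncoding classes", {
  v <- make_variants(4, variant_classification = c("Missense_Mutation",
                                                   "Intron", "5'Flank",
                                                   "Splice_Site"))
  out <- exclude_noncoding(v, verbose = FALSE)
  expect_equal(out$variant_classification,
               c("Missense_Mutation", "Splice_Site"))
  silent <- make_variants(2, variant_classification = "Silent")
  expect_identical(exclude_noncoding(silent, verbose = FALSE), silent)
  expect_equal(nrow(exclude_noncoding(v[0, ], verbose = FALSE)), 0)
})

test_that("filter operations are idempotent and commute", {
  gen <- generate_cohort(cohort_config(
    n_genes = 40, seed = 11, noncoding_rate = 0.2, filter_fail_rate = 0.2,
    caller_dropout_rate = 0.2))
  v <- gen$cohort$variants
  f <- function(x) filter_tcga_variants(x, verbose = FALSE)
  g <- function(x) exclude_noncoding(x, verbose = FALSE)
  expect_identical(f(f(v)), f(v))
  expect_identical(g(g(v)), g(v))
  expect_identical(f(g(v)), g(f(v)))
})

test_that("is_nonsilent matches the non-silent definition", {
  expect_true(is_nonsilent("Splice_Site"))
  expect_true(is_nonsilent("Frame_Shift_Del"))
  expect_false(is_nonsilent("Silent"))
  expect_error(is_nonsilent("Intron"), "coding/splice")
})

test_that("stratify partitions samples by stage class and subgroup", {
  clin <- make_clin(paste0("S", 1:4), stage = c("I", "II", "III", "IV"))
  v <- make_variants(4, sample_id = paste0("S", 1:4))
  co <- new_cohort(v, clin)
  strata <- stratify(co, by = "stage_class")
  expect_equal(sort(names(strata)), c("early", "late"))
  expect_equal(nrow(strata$early$clinical), 2)
  expect_equal(nrow(strata$late$clinical), 2)

  # subgroup strata sized like the TCGA cohort
  clin2 <- make_clin(sprintf("T%03d", 1:336),
                     subgroup = rep(c("MSI_hypermutated", "CN_low", "CN_high"),
                                    c(141, 140, 55)))
  co2 <- new_cohort(make_variants(1, sample_id = "T001"), clin2)
  sub <- stratify(co2, by = "subgroup")
  expect_equal(vapply(sub, function(s) nrow(s$clinical), integer(1))[
    c("MSI_hypermutated", "CN_low", "CN_high")],
    c(MSI_hypermutated = 141L, CN_low = 140L, CN_high = 55L))
  # partition: stratum sizes sum to cohort size
  expect_equal(sum(vapply(sub, function(s) nrow(s$clinical), integer(1))), 336)

  # unknown stage routed to its own stratum
  clin3 <- make_clin(paste0("U", 1:3), stage = c("I", "bad", "III"))
  co3 <- new_cohort(make_variants(1, sample_id = "U1"), clin3)
  s3 <- stratify(co3, by = "stage_class")
  expect_equal(nrow(s3$unknown$clinical), 1)
})

test_that("summarize_burden computes mean, range and reconciles totals", {
  clin <- make_clin(paste0("S", 1:3))
  v <- make_variants(6, sample_id = c("S2", "S2", "S3", "S3", "S3", "S3"))
  co <- new_cohort(v, clin)
  b <- summarize_burden(co)
  expect_equal(b$mean, 2)             # counts the zero-variant sample S1
  expect_equal(b$range, c(0L, 4L))
  expect_equal(b$mean * b$n_samples, b$total)

  one <- new_cohort(make_variants(1, sample_id = "S1"), make_clin("S1"))
  b1 <- summarize_burden(one)
  expect_equal(b1$mean, 1)
  expect_equal(b1$range, c(1L, 1L))
  expect_error(summarize_burden(new_cohort(v[0, ], clin[0, ])), "no samples")
})

test_that("cohort constructor enforces clinical linkage invariants", {
  clin <- make_clin(c("S1", "S2"))
  expect_error(new_cohort(make_variants(1, sample_id = "S9"), clin), "absent")
  dup <- make_clin(c("S1", "S1"))
  expect_error(new_cohort(make_variants(1, sample_id = "S1"), dup), "duplicate")
})

test_that("clinical TSVs parse with stage-class derivation", {
  path <- write_tsv_fixture(tibble::tibble(
    sample_id = c("A", "B", "C"), stage = c("II", "IV", "NA"),
    grade = c("G1", "G3", "G9"), subgroup = c("MSI_hypermutated", "CN_low", "?")))
  cl <- read_clinical(path)
  expect_equal(cl$stage_class, c("early", "late", "unknown"))
  expect_equal(cl$grade[3], "unknown")
  expect_equal(cl$subgroup[3], "unassigned")
})
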