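test_that("deletions inside a (C)7 tract are called in-tract", {
  # A T C C C C C C C G A : C run of 7, delete the C at 0-based offset 4
  call <- detect_homopolymer("DEL", "C", "-", "ATCCCCCCCGA", 4L)
  expect_equal(call$tract_base, "C")
  expect_equal(call$tract_length, 7L)
  expect_true(call$in_tract)

  # multi-base deletion fully inside the run
  call2 <- detect_homopolymer("DEL", "CC", "-", "ATCCCCCCCGA", 4L)
  expect_true(call2$in_tract)
  # deletion spanning beyond the run base is not a homopolymer event
  call3 <- detect_homopolymer("DEL", "CG", "-", "ATCCCCCCCGA", 8L)
  expect_false(call3$in_tract)
})

test_that("insertions flanked by a short run stay below the tract floor", {
  # C C A A A A G G, insert an A after 0-based offset 5 (the last A)
  call <- detect_homopolymer("INS", "-", "A", "CCAAAAGG", 5L)
  expect_equal(call$tract_length, 4L)
  expect_false(call$in_tract)
  # the run adjoins across the insertion point
  call2 <- detect_homopolymer("INS", "-", "A", "CCAAAAAGG", 2L)
  expect_equal(call2$tract_length, 5L)
  expect_true(call2$in_tract)
  # inserting a base with no matching flank
  call3 <- detect_homopolymer("INS", "-", "T", "CCAAAAGG", 5L)
  expect_equal(call3$tract_length, 0L)
  expect_false(call3$in_tract)
})

test_that("dinucleotide repeats never qualify as homopolymer tracts", {
  call <- detect_homopolymer("DEL", "G", "-", "ATATGATAT", 4L)
  expect_equal(call$tract_length, 1L)
  expect_false(call$in_tract)
})

test_that("homopolymer calls handle contracts and missing context", {
  expect_error(detect_homopolymer("SNP", "A", "T", "AAAA", 1L), "indels only")
  un <- detect_homopolymer("DEL", "A", "-", NA_character_, NA_integer_)
  expect_false(un$callable)
  expect_true(is.na(un$in_tract))
  expect_warning(
    mis <- detect_homopolymer("DEL", "T", "-", "ACCCCCCCGA", 4L),
    "uncallable")
  expect_false(mis$callable)
})

test_that("homopolymer calls are invariant under reverse complement", {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  withr::with_seed(31, {
    for (i in 1:50) {
      tract <- sample(3:9, 1)
      base <- sample(c("A", "C", "G", "T"), 1)
      other <- setdiff(c("A", "C", "G", "T"), base)
      win <- paste(c(sample(other, 6, TRUE), rep(base, tract),
                     sample(other, 6, TRUE)), collapse = "")
      n <- nchar(win)
      off <- 6L + sample(seq_len(tract), 1) - 1L  # 0-based, inside the tract
      f <- detect_homopolymer("DEL", base, "-", win, off)
      r <- detect_homopolymer("DEL", rc(base), "-", rc(win), n - off - 1L)
      expect_equal(f$tract_length, r$tract_length)
      expect_identical(f$in_tract, r$in_tract)

      fi <- detect_homopolymer("INS", "-", base, win, off)
      ri <- detect_homopolymer("INS", "-", rc(base), rc(win), n - off - 2L)
      expect_equal(fi$tract_length, ri$tract_length)
      expect_identical(fi$in_tract, ri$in_tract)
    }
  })
})

test_that("recurrence counts distinct samples per protein change", {
  v <- make_variants(4,
    sample_id = c("S1", "S2", "S3", "S3"),
    gene = "KLF3",
    pos = c(1L, 2L, 3L, 4L),
    protein_change = c("K106Nfs*21", "K106Nfs*21", "P226Rfs*52", "P226Rfs*52"))
  rec <- recurrence_table(v)
  expect_equal(rec$n_samples[rec$protein_change == "K106Nfs*21"], 2L)
  expect_true(rec$recurrent[rec$protein_change == "K106Nfs*21"])
  # same change twice in one sample counts once
  expect_equal(rec$n_samples[rec$protein_change == "P226Rfs*52"], 1L)
  expect_false(rec$recurrent[rec$protein_change == "P226Rfs*52"])
})

test_that("fisher_2x2 matches the enumeration oracle and fisher.test", {
  expect_equal(fisher_2x2(1, 1, 1, 1)$p_value, 1)
  expect_error(fisher_2x2(0, 0, 0, 0), "all-zero")
  expect_equal(fisher_2x2(5, 0, 0, 5)$odds_ratio, Inf)

  withr::with_seed(13, {
    for (i in 1:200) {
      cells <- rpois(4, 6)
      if (sum(cells) == 0) cells[1] <- 1
      got <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got$p_value,
                   fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
      expect_equal(got$p_value,
                   fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
      # invariance under transpose
      expect_equal(got$p_value,
                   fisher_2x2(cells[1], cells[3], cells[2], cells[4])$p_value,
                   tolerance = 1e-12)
    }
  })
})

test_that("frequency_table totals equal stratify's stratum sizes", {
  gen <- generate_cohort(cohort_config(
    n_genes = 60, seed = 41,
    drivers = driver_spec("KLF3", 0.1, 0.3, subgroup = "MSI_hypermutated",
                          indel_homopolymer_fraction = 0.8,
                          hotspots = "K106Nfs*21")))
  co <- gen$cohort
  tab <- suppressWarnings(frequency_table(co, c("KLF3", "NOT_A_GENE"),
                                          by = "subgroup"))
  sizes <- vapply(stratify(co, by = "subgroup"),
                  function(s) nrow(s$clinical), integer(1))
  for (lab in names(sizes)) {
    expect_equal(unique(tab$n_total[tab$stratum == lab]), unname(sizes[lab]))
  }
  expect_equal(unique(tab$n_total[tab$stratum == "all"]), nrow(co$clinical))
  expect_true(all(tab$n_mutated[tab$gene == "NOT_A_GENE"] == 0))
  # percent at one decimal: 20 of 141 would print 14.2
  expect_equal(tab$percent, round(100 * tab$n_mutated / tab$n_total, 1))
  # per-stratum counts match an independent tally over the raw tables
  # (driver events are MSI-restricted but background hits land anywhere)
  v <- co$variants
  cl <- co$clinical
  mutated_samples <- unique(v$sample_id[v$gene == "KLF3" &
                                          is_nonsilent(v$variant_classification)])
  for (sub in c("MSI_hypermutated", "CN_low", "CN_high")) {
    expected <- sum(cl$sample_id[cl$subgroup == sub] %in% mutated_samples)
    expect_equal(tab$n_mutated[tab$gene == "KLF3" & tab$stratum == sub],
                 expected)
  }
  # planted driver events only ever hit MSI-hypermutated samples
  drv <- gen$truth[gen$truth$origin %in% c("driver_snv", "driver_homopolymer"), ]
  expect_true(all(cl$subgroup[match(drv$sample_id, cl$sample_id)] ==
                    "MSI_hypermutated"))
})

test_that("missense consensus requires three of four impact labels", {
  expect_true(missense_consensus(c(MutationAssessor = "high",
                                   PROVEAN = "deleterious",
                                   SIFT = "damaging",
                                   PolyPhen2 = "benign"))$impact)
  expect_true(missense_consensus(c(MutationAssessor = "high",
                                   PROVEAN = "deleterious",
                                   SIFT = "damaging",
                                   PolyPhen2 = "probably-damaging"))$impact)
  # two impact labels with two predictors missing is not a consensus
  expect_false(missense_consensus(c(MutationAssessor = "high",
                                    PROVEAN = "deleterious"))$impact)
  expect_error(missense_consensus(c(CADD = "high")), "unknown predictor")
})
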