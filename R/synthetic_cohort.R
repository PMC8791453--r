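default_cells <- function() {
  tibble::tribble(
    ~stage_class, ~subgroup,          ~n,
    "early",      "MSI_hypermutated", 114L,
    "early",      "CN_low",           119L,
    "early",      "CN_high",           37L,
    "late",       "MSI_hypermutated",  27L,
    "late",       "CN_low",            21L,
    "late",       "CN_high",           18L
  )
}

default_mu <- function() {
  c(MSI_hypermutated = 2e-5, CN_low = 2e-6, CN_high = 2e-6,
    POLE_ultramutated = 2e-4, unassigned = 2e-6)
}

#' Driver gene specification for the synthetic cohort
#'
#' @param gene Gene symbol.
#' @param r_early,r_late Probability that an eligible early-/late-stage
#'   tumor acquires a driver mutation in the gene.
#' @param subgroup Molecular subgroup the driver is restricted to, or `NA`
#'   for all subgroups.
#' @param indel_homopolymer_fraction Fraction of driver events realized as
#'   1-bp deletions inside a planted homopolymer tract (with context
#'   window emitted), the MSI-target signature; the rest are missense
#'   SNVs.
#' @param hotspots Character vector of protein-change strings sampled for
#'   homopolymer indel events (recurrence is string-based).
#' @return One-row tibble; bind rows to specify several drivers.
#' @export
driver_spec <- function(gene, r_early, r_late, subgroup = NA_character_,
                        indel_homopolymer_fraction = 0,
                        hotspots = character(0)) {
  stopifnot(r_early >= 0, r_early <= 1, r_late >= 0, r_late <= 1,
            indel_homopolymer_fraction >= 0, indel_homopolymer_fraction <= 1)
  tibble::tibble(gene = gene, r_early = r_early, r_late = r_late,
                 subgroup = subgroup,
                 indel_homopolymer_fraction = indel_homopolymer_fraction,
                 hotspots = list(hotspots))
}

empty_drivers <- function() {
  tibble::tibble(gene = character(0), r_early = numeric(0),
                 r_late = numeric(0), subgroup = character(0),
                 indel_homopolymer_fraction = numeric(0),
                 hotspots = list())
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the non-ultramutated TCGA EEC study conditions: the
#' six stage-by-subgroup cell sizes of the 336-tumor cohort, a
#' hypermutated MSI background (`mu` 2e-5, roughly 20 mutations/Mb)
#' an order of magnitude above the copy-number subgroups (2e-6), per-gene
#' mutation-rate factors drawn lognormal with median 1 and 90th percentile
#' 3.9, and gene lengths lognormal around 1500 bp. All noise channels
#' (caller dropout, FILTER failures, depth/VAF violations, dbSNP
#' contamination, noncoding classes) default to zero so that closed-loop
#' filter tests can enable them one at a time.
#'
#' @param cells Tibble with `stage_class`, `subgroup`, `n` (samples per
#'   cell).
#' @param mu Named vector of background rates per subgroup.
#' @param n_genes Size of the gene universe.
#' @param gene_length,gene_length_sdlog Median and lognormal sd of gene
#'   lengths (sd 0 gives constant lengths); truncated to [300, 8000].
#' @param fg_median,fg_sdlog Median and lognormal sd of per-gene mutation
#'   rate factors (defaults give a 90th percentile of 3.9).
#' @param drivers Tibble from [driver_spec()] rows (possibly empty).
#' @param mis_detection Probability a true driver mutation is missed by
#'   sequencing/calling.
#' @param caller_style `"tcga"` (MuTect SNVs / Indelocator indels in a
#'   CENTERS-style column) or `"nhgri"` (Strelka/Shimmer/SomaticSniper/
#'   MuTect consensus-style provenance).
#' @param silent_ratio Rate of background silent variants relative to the
#'   non-silent background.
#' @param filter_fail_rate,depth_violation_rate,germline_vaf_rate,dbsnp_contamination_rate,dbsnp_decoy_rate,caller_dropout_rate,noncoding_rate
#'   Per-variant probabilities of planting the corresponding filter
#'   violation (decoys are dbSNP entries with MAF <= 5% that must be
#'   retained).
#' @param seed Random seed; recorded in the output metadata.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(cells = default_cells(),
                          mu = default_mu(),
                          n_genes = 300,
                          gene_length = 1500, gene_length_sdlog = 0.35,
                          fg_median = 1,
                          fg_sdlog = log(3.9) / stats::qnorm(0.9),
                          drivers = empty_drivers(),
                          mis_detection = 0.1,
                          caller_style = c("tcga", "nhgri"),
                          silent_ratio = 0.33,
                          filter_fail_rate = 0,
                          depth_violation_rate = 0,
                          germline_vaf_rate = 0,
                          dbsnp_contamination_rate = 0,
                          dbsnp_decoy_rate = 0,
                          caller_dropout_rate = 0,
                          noncoding_rate = 0,
                          seed = 1L) {
  caller_style <- match.arg(caller_style)
  rates <- c(mis_detection = mis_detection, silent_ratio = silent_ratio,
             filter_fail_rate = filter_fail_rate,
             depth_violation_rate = depth_violation_rate,
             germline_vaf_rate = germline_vaf_rate,
             dbsnp_contamination_rate = dbsnp_contamination_rate,
             dbsnp_decoy_rate = dbsnp_decoy_rate,
             caller_dropout_rate = caller_dropout_rate,
             noncoding_rate = noncoding_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must be in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$n < 0)) stop("cell sizes must be non-negative", call. = FALSE)
  missing_mu <- setdiff(unique(cells$subgroup), names(mu))
  if (length(missing_mu) > 0) {
    stop("no background mu for subgroup(s): ",
         paste(missing_mu, collapse = ", "), call. = FALSE)
  }
  structure(list(cells = cells, mu = mu, n_genes = n_genes,
                 gene_length = gene_length,
                 gene_length_sdlog = gene_length_sdlog,
                 fg_median = fg_median, fg_sdlog = fg_sdlog,
                 drivers = drivers, mis_detection = mis_detection,
                 caller_style = caller_style, silent_ratio = silent_ratio,
                 filter_fail_rate = filter_fail_rate,
                 depth_violation_rate = depth_violation_rate,
                 germline_vaf_rate = germline_vaf_rate,
                 dbsnp_contamination_rate = dbsnp_contamination_rate,
                 dbsnp_decoy_rate = dbsnp_decoy_rate,
                 caller_dropout_rate = caller_dropout_rate,
                 noncoding_rate = noncoding_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

rand_window <- function(n_windows, width = 21) {
  vapply(seq_len(n_windows),
         function(i) paste(rand_base(width), collapse = ""),
         character(1))
}

# 21-bp window with a 7-base homopolymer tract centered; the deleted base
# sits at 0-based offset 10 (inside the tract).
homopolymer_window <- function(base, width = 21, tract = 7) {
  flank <- (width - tract) / 2
  other <- setdiff(c("A", "C", "G", "T"), base)
  left <- sample(other, flank, replace = TRUE)
  right <- sample(other, flank, replace = TRUE)
  paste(c(left, rep(base, tract), right), collapse = "")
}

#' Generate a synthetic EEC mutation cohort with a ground-truth ledger
#'
#' Per sample, each gene acquires a background non-silent mutation with
#' probability `p0(gene)` from the binomial background model under the
#' sample's subgroup-specific `mu` (plus silent variants at
#' `silent_ratio` times that rate). Driver genes additionally mutate
#' eligible samples with probability `r` for the sample's stage class,
#' observed with probability `1 - mis_detection`; MSI-style drivers are
#' realized as 1-bp deletions inside planted homopolymer windows with
#' hotspot protein-change strings. Read support, caller provenance,
#' FILTER designations and dbSNP membership are fabricated, with each
#' configured noise channel planting violations that the ledger records,
#' so that every filtering rule has known true and false positives.
#'
#' A single seeded random stream drives all sampling in documented order,
#' so identical configs give byte-identical output files.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `cohort` (an `eec_cohort`),
#'   `truth` (per-variant ledger: origin, planted violations, dbSNP
#'   membership, homopolymer flag), `driver_events` (every planted driver
#'   event, including those hidden by mis-detection), `dbsnp` (lookup
#'   consistent with the planted contamination plus decoys), `genes`
#'   (per-gene length and rate factor), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_genes <- config$n_genes
  genes <- tibble::tibble(
    gene = sprintf("G%04d", seq_len(n_genes)),
    chrom = paste0("chr", (seq_len(n_genes) - 1) %% 22 + 1),
    start = 1e6 * seq_len(n_genes),
    L = if (config$gene_length_sdlog > 0) {
      pmin(8000, pmax(300, round(stats::rlnorm(n_genes,
                                               log(config$gene_length),
                                               config$gene_length_sdlog))))
    } else rep(config$gene_length, n_genes),
    f_g = if (config$fg_sdlog > 0) {
      stats::rlnorm(n_genes, log(config$fg_median), config$fg_sdlog)
    } else rep(config$fg_median, n_genes)
  )
  drivers <- config$drivers
  if (nrow(drivers) > 0) {
    if (nrow(drivers) > n_genes) stop("more drivers than genes", call. = FALSE)
    genes$gene[seq_len(nrow(drivers))] <- drivers$gene
  }

  # clinical table
  cells <- config$cells[config$cells$n > 0, , drop = FALSE]
  clin_rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    stage_class <- cells$stage_class[i]
    figo <- if (stage_class == "early") {
      sample(c("I", "II"), n, replace = TRUE, prob = c(0.7, 0.3))
    } else {
      sample(c("III", "IV"), n, replace = TRUE, prob = c(0.75, 0.25))
    }
    tibble::tibble(figo_stage = figo, subgroup = cells$subgroup[i])
  })
  clin <- dplyr::bind_rows(clin_rows)
  clin <- make_clinical(sprintf("S%04d", seq_len(nrow(clin))),
                        clin$figo_stage,
                        sample(c("G1", "G2", "G3"), nrow(clin),
                               replace = TRUE, prob = c(0.25, 0.3, 0.45)),
                        clin$subgroup)

  # per-subgroup, per-gene background probabilities
  p0_by_subgroup <- lapply(config$mu, function(mu_s) {
    -expm1(0.75 * genes$L * log1p(-pmin(1, mu_s * genes$f_g)))
  })

  events <- list()
  driver_events <- list()
  driver_idx <- if (nrow(drivers) > 0) {
    stats::setNames(seq_len(nrow(drivers)), drivers$gene)
  } else integer(0)

  for (s in seq_len(nrow(clin))) {
    sid <- clin$sample_id[s]
    p0 <- p0_by_subgroup[[clin$subgroup[s]]]
    bg <- which(stats::runif(n_genes) < p0)
    sil <- which(stats::runif(n_genes) < p0 * config$silent_ratio)
    if (length(bg) > 0) {
      events[[length(events) + 1]] <- tibble::tibble(
        sample_id = sid, gene_i = bg, origin = "background")
    }
    if (length(sil) > 0) {
      events[[length(events) + 1]] <- tibble::tibble(
        sample_id = sid, gene_i = sil, origin = "silent")
    }
    for (d in seq_len(nrow(drivers))) {
      dr <- drivers[d, ]
      if (!is.na(dr$subgroup) && dr$subgroup != clin$subgroup[s]) next
      if (clin$stage_class[s] == "unknown") next
      r <- if (clin$stage_class[s] == "early") dr$r_early else dr$r_late
      if (stats::runif(1) >= r) next
      detected <- stats::runif(1) >= config$mis_detection
      as_indel <- stats::runif(1) < dr$indel_homopolymer_fraction
      driver_events[[length(driver_events) + 1]] <- tibble::tibble(
        sample_id = sid, gene = dr$gene, stage_class = clin$stage_class[s],
        detected = detected, homopolymer_indel = as_indel)
      if (detected) {
        events[[length(events) + 1]] <- tibble::tibble(
          sample_id = sid, gene_i = driver_idx[[dr$gene]],
          origin = if (as_indel) "driver_homopolymer" else "driver_snv")
      }
    }
  }
  ev <- dplyr::bind_rows(events)
  if (nrow(ev) == 0) stop("configuration generated zero variants", call. = FALSE)
  driver_events <- if (length(driver_events) > 0) {
    dplyr::bind_rows(driver_events)
  } else {
    tibble::tibble(sample_id = character(0), gene = character(0),
                   stage_class = character(0), detected = logical(0),
                   homopolymer_indel = logical(0))
  }

  v <- fabricate_variants(ev, genes, drivers, config)
  truth <- v$truth
  variants <- v$variants

  dbsnp <- variants[truth$in_dbsnp,
                    c("chrom", "pos", "ref_allele", "alt_allele")]
  names(dbsnp) <- c("chrom", "pos", "ref", "alt")
  dbsnp$maf <- truth$dbsnp_maf[truth$in_dbsnp]

  structure(list(
    cohort = new_cohort(variants, clin, name = "synthetic"),
    truth = truth,
    driver_events = driver_events,
    dbsnp = dbsnp,
    genes = genes,
    config = config
  ), class = "synthetic_cohort")
}

fabricate_variants <- function(ev, genes, drivers, config) {
  n <- nrow(ev)
  g <- genes[ev$gene_i, ]
  style <- config$caller_style

  # variant type and classification by origin
  vtype <- character(n)
  vclass <- character(n)
  is_bg <- ev$origin == "background"
  is_sil <- ev$origin == "silent"
  is_hot <- ev$origin == "driver_homopolymer"
  is_dsnv <- ev$origin == "driver_snv"

  vtype[is_bg] <- sample(c("SNP", "INS", "DEL"), sum(is_bg), replace = TRUE,
                         prob = c(0.85, 0.07, 0.08))
  vclass[is_bg & vtype == "SNP"] <-
    sample(c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site"),
           sum(is_bg & vtype == "SNP"), replace = TRUE,
           prob = c(0.8, 0.12, 0.08))
  vclass[is_bg & vtype == "INS"] <-
    sample(c("Frame_Shift_Ins", "In_Frame_Ins"),
           sum(is_bg & vtype == "INS"), replace = TRUE, prob = c(0.8, 0.2))
  vclass[is_bg & vtype == "DEL"] <-
    sample(c("Frame_Shift_Del", "In_Frame_Del"),
           sum(is_bg & vtype == "DEL"), replace = TRUE, prob = c(0.8, 0.2))
  vtype[is_sil] <- "SNP"; vclass[is_sil] <- "Silent"
  vtype[is_hot] <- "DEL"; vclass[is_hot] <- "Frame_Shift_Del"
  vtype[is_dsnv] <- "SNP"; vclass[is_dsnv] <- "Missense_Mutation"

  # alleles and homopolymer contexts
  ref <- character(n); alt <- character(n)
  context_seq <- rep(NA_character_, n)
  context_offset <- rep(NA_integer_, n)
  snp <- vtype == "SNP"
  ref[snp] <- rand_base(sum(snp))
  alt[snp] <- vapply(ref[snp],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  ins <- vtype == "INS"
  ref[ins] <- "-"; alt[ins] <- rand_base(sum(ins))
  del <- vtype == "DEL" & !is_hot
  ref[del] <- rand_base(sum(del)); alt[del] <- "-"
  # non-tract indels still carry a context window so tract calls are FALSE,
  # not uncallable
  indel <- vtype != "SNP" & !is_hot
  context_seq[indel] <- rand_window(sum(indel))
  context_offset[indel] <- 10L
  for (i in which(del)) {
    # window must contain the deleted base at the offset
    w <- strsplit(context_seq[i], "")[[1]]
    w[11] <- ref[i]
    context_seq[i] <- paste(w, collapse = "")
  }
  if (any(is_hot)) {
    hot_base <- sample(c("A", "C"), sum(is_hot), replace = TRUE)
    context_seq[is_hot] <- vapply(hot_base, homopolymer_window, character(1))
    context_offset[is_hot] <- 10L
    ref[is_hot] <- hot_base
    alt[is_hot] <- "-"
  }

  # protein changes: hotspots for homopolymer drivers, positional strings
  # for other drivers
  protein_change <- rep(NA_character_, n)
  if (nrow(drivers) > 0) {
    for (d in seq_len(nrow(drivers))) {
      hs <- drivers$hotspots[[d]]
      rows_hot <- which(is_hot & g$gene == drivers$gene[d])
      if (length(rows_hot) > 0) {
        protein_change[rows_hot] <- if (length(hs) > 0) {
          sample(hs, length(rows_hot), replace = TRUE)
        } else {
          sprintf("K%dNfs*%d", sample(50:400, length(rows_hot), replace = TRUE),
                  sample(5:60, length(rows_hot), replace = TRUE))
        }
      }
      rows_snv <- which(is_dsnv & g$gene == drivers$gene[d])
      if (length(rows_snv) > 0) {
        protein_change[rows_snv] <- sprintf(
          "%s%d%s", sample(LETTERS, length(rows_snv), replace = TRUE),
          sample(30:400, length(rows_snv), replace = TRUE),
          sample(LETTERS, length(rows_snv), replace = TRUE))
      }
    }
  }

  # read support: depths comfortably above filter minima unless violated
  t_depth <- 14L + stats::rpois(n, 56)
  n_depth <- 8L + stats::rpois(n, 57)
  t_alt <- pmax(1L, stats::rbinom(n, t_depth, 0.3))
  n_alt <- rep(0L, n)

  # caller provenance and FILTER
  callers <- character(n)
  if (style == "tcga") {
    extra <- sample(c("", "|MUSE", "|RADIA", "|MUSE|RADIA"), n, replace = TRUE)
    callers[snp] <- paste0("MUTECT", extra[snp])
    callers[!snp] <- "INDELOCATOR"
  } else {
    callers[snp] <- "Strelka|Shimmer|SomaticSniper|MuTect"
    callers[!snp] <- sample(c("Strelka", "Shimmer", "Strelka|Shimmer"),
                            sum(!snp), replace = TRUE)
  }
  filter_status <- sample(c("PASS", "WGA", "Native_WGA_mix"), n,
                          replace = TRUE, prob = c(0.8, 0.1, 0.1))

  # noise channels; drivers are kept clean so pipelines can recover them
  bg_like <- is_bg | is_sil
  violations <- vector("list", n)
  plant <- function(rate, eligible) {
    which(eligible & stats::runif(n) < rate)
  }

  idx <- plant(config$noncoding_rate, is_bg & snp)
  vclass[idx] <- sample(noncoding_classifications(), length(idx),
                        replace = TRUE)
  for (i in idx) violations[[i]] <- c(violations[[i]], "noncoding")

  idx <- plant(config$filter_fail_rate, bg_like)
  filter_status[idx] <- "nonpreferredpair"
  for (i in idx) violations[[i]] <- c(violations[[i]], "filter_status")

  idx <- plant(config$depth_violation_rate, bg_like)
  for (i in idx) {
    if (stats::runif(1) < 0.5) {
      t_depth[i] <- sample(1:13, 1)
      t_alt[i] <- min(t_alt[i], t_depth[i])
    } else {
      n_depth[i] <- sample(1:7, 1)
    }
    violations[[i]] <- c(violations[[i]], "read_support")
  }

  idx <- plant(config$germline_vaf_rate, bg_like)
  for (i in idx) {
    vaf <- stats::runif(1, 0.04, 0.4)
    n_alt[i] <- max(ceiling(vaf * n_depth[i]), floor(0.03 * n_depth[i]) + 1L)
    n_alt[i] <- min(n_alt[i], n_depth[i])
    violations[[i]] <- c(violations[[i]], "germline_vaf")
  }

  in_dbsnp <- rep(FALSE, n)
  dbsnp_maf <- rep(NA_real_, n)
  idx <- plant(config$dbsnp_contamination_rate, bg_like)
  in_dbsnp[idx] <- TRUE
  dbsnp_maf[idx] <- ifelse(snp[idx], stats::runif(length(idx), 0.051, 0.5),
                           stats::runif(length(idx), 0.001, 0.5))
  for (i in idx) violations[[i]] <- c(violations[[i]], "dbsnp")

  idx <- plant(config$dbsnp_decoy_rate, bg_like & snp & !in_dbsnp)
  in_dbsnp[idx] <- TRUE
  dbsnp_maf[idx] <- stats::runif(length(idx), 0.001, 0.049)

  idx <- plant(config$caller_dropout_rate, bg_like)
  for (i in idx) {
    callers[i] <- if (style == "tcga") {
      if (snp[i]) "MUSE|RADIA" else "VARSCANI"
    } else {
      if (snp[i]) {
        paste(sample(c("Strelka", "Shimmer", "SomaticSniper", "MuTect"), 3),
              collapse = "|")
      } else "SomaticSniper"
    }
    violations[[i]] <- c(violations[[i]], "caller_consensus")
  }

  variants <- tibble::tibble(
    sample_id = ev$sample_id,
    gene = g$gene,
    chrom = g$chrom,
    # unique, deterministic positions within each gene: dbSNP keys are exact
    pos = as.integer(g$start + stats::ave(seq_len(n), g$gene, FUN = seq_along)),
    ref_allele = ref,
    alt_allele = alt,
    variant_type = vtype,
    variant_classification = vclass,
    filter_status = filter_status,
    callers = callers,
    t_depth = t_depth,
    t_alt_count = t_alt,
    n_depth = n_depth,
    n_alt_count = n_alt,
    protein_change = protein_change,
    context_seq = context_seq,
    context_offset = context_offset
  )
  truth <- tibble::tibble(
    variant_id = seq_len(n),
    sample_id = ev$sample_id,
    gene = g$gene,
    chrom = variants$chrom,
    pos = variants$pos,
    ref_allele = variants$ref_allele,
    alt_allele = variants$alt_allele,
    origin = ev$origin,
    violations = vapply(violations, function(v) {
      if (is.null(v)) "" else paste(v, collapse = ",")
    }, character(1)),
    in_dbsnp = in_dbsnp,
    dbsnp_maf = dbsnp_maf,
    homopolymer = is_hot
  )
  list(variants = variants, truth = truth)
}

#' Emit the dbSNP lookup consistent with the planted contamination
#'
#' Every variant the ledger marks as a germline contaminant appears in the
#' lookup (SNVs with MAF > 0.05, indels at any MAF), alongside low-MAF
#' decoy entries that the dbSNP filter must retain.
#'
#' @param gen A `synthetic_cohort` from [generate_cohort()].
#' @return dbSNP lookup tibble (see [read_dbsnp()]).
#' @export
emit_dbsnp <- function(gen) {
  stopifnot(inherits(gen, "synthetic_cohort"))
  gen$dbsnp
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Produces `maf.tsv` (generic dialect, with inline context columns),
#' `clinical.tsv`, `dbsnp.tsv`, `truth.tsv`, `genes.tsv` (the per-gene
#' length and rate factor draws, usable as `gene_params` in [smg_scan()]),
#' and `meta.yaml` (seed and scalar config). Identical configs give
#' byte-identical files.
#'
#' @param gen A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(gen$cohort$variants, file.path(dir, "maf.tsv"), dialect = "generic")
  cl <- gen$cohort$clinical
  readr::write_tsv(tibble::tibble(sample_id = cl$sample_id,
                                  stage = cl$figo_stage, grade = cl$grade,
                                  subgroup = cl$subgroup),
                   file.path(dir, "clinical.tsv"), progress = FALSE)
  readr::write_tsv(gen$dbsnp, file.path(dir, "dbsnp.tsv"), progress = FALSE)
  readr::write_tsv(gen$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(gen$genes, file.path(dir, "genes.tsv"), progress = FALSE)
  cfg <- gen$config
  yaml::write_yaml(list(seed = cfg$seed, n_genes = cfg$n_genes,
                        caller_style = cfg$caller_style,
                        mu = as.list(cfg$mu)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}
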