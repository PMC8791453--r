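test_that("background_rate matches the closed form and its limits", {
  expect_equal(background_rate(background_model(0)), 0)
  # mu * f_g = 1 saturates
  expect_equal(background_rate(background_model(1, f_g = 1)), 1)
  m <- background_model(1e-5)
  expect_equal(background_rate(m), 1 - (1 - 1e-5 * 3.9)^(0.75 * 1500),
               tolerance = 1e-12)
  expect_error(background_model(0.5, f_g = 3.9), "exceeds 1")
})

test_that("background_rate approaches mu*f_g*(3/4)L in the small-rate limit", {
  for (mu in c(1e-9, 1e-8, 1e-7)) {
    p0 <- background_rate(background_model(mu))
    expect_equal(p0, mu * 3.9 * 0.75 * 1500, tolerance = 0.01)
  }
})

test_that("signal_rate adds the discounted driver frequency, capped at 1", {
  expect_equal(signal_rate(0.3, 0), 0.3)
  expect_equal(signal_rate(0.05, 0.10, 0.1), 0.14)
  expect_equal(signal_rate(0.99, 0.5, 0), 1)
  expect_true(all(signal_rate(0.2, seq(0, 1, 0.1)) >= 0.2))
})

test_that("gene_pvalue is the inclusive upper binomial tail", {
  expect_equal(gene_pvalue(0, 10, 0.3), 1)
  expect_equal(gene_pvalue(2, 2, 0.5), 0.25)
  expect_error(gene_pvalue(1, 10, 1.2), "p0")
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(1:1000, 1)
      p0 <- runif(1, 0, 0.3)
      x <- sample(0:n, 1)
      expect_equal(gene_pvalue(x, n, p0), pvalue_oracle(x, n, p0),
                   tolerance = 1e-12)
    }
  })
})

test_that("detect_power has correct size and limits", {
  m <- background_model(1e-6)
  # under the null the rejection rate cannot exceed the per-test level
  expect_lte(detect_power(100, m, r = 0), m$alpha / m$k)
  m0 <- background_model(1e-6, m = 0)
  expect_gt(detect_power(100, m0, r = 1), 0.999999)
})

test_that("detect_power is monotone in r, n and mis-detection", {
  m <- background_model(2e-6)
  pow_r <- vapply(seq(0, 0.5, 0.05), function(r) detect_power(120, m, r),
                  numeric(1))
  expect_true(all(diff(pow_r) >= -1e-12))
  pow_n <- vapply(c(30, 60, 120, 240, 480), function(n) detect_power(n, m, 0.1),
                  numeric(1))
  expect_true(all(diff(pow_n) >= -1e-12))
  pow_m <- vapply(seq(0, 0.9, 0.1), function(md) {
    detect_power(120, background_model(2e-6, m = md), 0.1)
  }, numeric(1))
  expect_true(all(diff(pow_m) <= 1e-12))
})

test_that("power_grid cells equal detect_power and rise with r", {
  m <- background_model(1e-6)
  pg <- power_grid(100, m, mu_values = 1e-6, r_values = 0.2)
  expect_equal(unname(pg$power[1, 1]), detect_power(100, m, 0.2))
  pg2 <- power_grid(100, m, mu_values = c(1e-7, 1e-6, 1e-5),
                    r_values = seq(0.02, 0.3, 0.04))
  expect_true(all(apply(pg2$power, 1, function(row) all(diff(row) >= -1e-12))))
  df <- as.data.frame(pg2)
  expect_equal(nrow(df), 3 * 8)
})

test_that("smg_scan deduplicates mutated samples per gene", {
  clin <- make_clin(c("S1", "S2"))
  v <- make_variants(3, sample_id = c("S1", "S1", "S2"),
                     gene = c("TP53", "TP53", "PTEN"),
                     pos = c(1L, 2L, 3L))
  res <- smg_scan(new_cohort(v, clin), background_model(1e-6))
  expect_equal(res$n_mutated[res$gene == "TP53"], 1L)  # two variants, one sample
  expect_equal(res$n_tumors, rep(2L, 2))
  expect_error(smg_scan(new_cohort(v[0, ], clin), background_model(1e-6)),
               "empty cohort")
})

test_that("a strongly mutated planted driver outranks every background gene", {
  m <- background_model(1e-6, f_g = 3.9)
  hits <- 0L
  for (seed in 1:20) {
    cfg <- cohort_config(
      cells = tibble::tibble(stage_class = "late",
                             subgroup = "MSI_hypermutated", n = 100L),
      mu = c(MSI_hypermutated = 1e-6), n_genes = 100,
      gene_length_sdlog = 0, fg_median = 3.9, fg_sdlog = 0,
      drivers = driver_spec("DRV1", r_early = 0.3, r_late = 0.3),
      seed = seed)
    gen <- generate_cohort(cfg)
    res <- smg_scan(gen$cohort, m)
    drv_p <- res$p_value[res$gene == "DRV1"]
    if (length(drv_p) == 1 && all(drv_p < res$p_value[res$gene != "DRV1"])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("null-cohort p-values are stochastically no smaller than uniform", {
  cfg <- cohort_config(
    cells = tibble::tibble(stage_class = "early", subgroup = "CN_low", n = 200L),
    mu = c(CN_low = 1e-6), n_genes = 300,
    gene_length_sdlog = 0, fg_median = 3.9, fg_sdlog = 0, seed = 77)
  res <- smg_scan(generate_cohort(cfg)$cohort, background_model(1e-6))
  # genes never mutated carry an implicit p of 1; with those included the
  # discreteness of the binomial tail makes the test conservative, so the
  # empirical cdf sits at or below the uniform line
  p_all <- c(res$p_value, rep(1, 300 - nrow(res)))
  grid <- seq(0.05, 0.95, 0.05)
  ecdf_vals <- vapply(grid, function(t) mean(p_all <= t), numeric(1))
  expect_true(all(ecdf_vals <= grid + 0.05))
})

test_that("gene-specific parameters recalibrate the scan", {
  clin <- make_clin(paste0("S", 1:50))
  v <- make_variants(10, sample_id = paste0("S", 1:10), gene = "LONGGENE")
  co <- new_cohort(v, clin)
  m <- background_model(1e-5)
  flat <- smg_scan(co, m)
  # declaring the gene long and mutation-prone raises its background and
  # weakens the evidence
  params <- tibble::tibble(gene = "LONGGENE", f_g = 20, L = 8000)
  calib <- smg_scan(co, m, gene_params = params)
  expect_gt(calib$p_value, flat$p_value)
  expect_equal(calib$p_value,
               pvalue_oracle(10, 50, background_rate(1e-5, f_g = 20, L = 8000)),
               tolerance = 1e-12)
  # genes absent from the table keep the model constants
  other <- smg_scan(co, m, gene_params = tibble::tibble(
    gene = "ELSEWHERE", f_g = 20, L = 8000))
  expect_equal(other$p_value, flat$p_value)
})

test_that("gene-specific backgrounds control heterogeneous null cohorts", {
  # heterogeneous f_g draws; the scan knows each gene's true parameters
  clean <- 0L
  for (seed in 301:310) {
    cfg <- cohort_config(
      cells = tibble::tibble(stage_class = "late", subgroup = "CN_low",
                             n = 80L),
      mu = c(CN_low = 5e-6), n_genes = 150, seed = seed)
    gen <- generate_cohort(cfg)
    params <- gen$genes[, c("gene", "f_g", "L")]
    res <- smg_scan(gen$cohort, background_model(5e-6),
                    gene_params = params) |>
      adjust_gene_results(n_tests = 150)
    if (!any(res$q_value <= 0.10)) clean <- clean + 1L
  }
  expect_gte(clean, 9L)
})

test_that("estimate_background_mu inverts the generator's background rate", {
  cfg <- cohort_config(
    cells = tibble::tibble(stage_class = "early", subgroup = "CN_low", n = 400L),
    mu = c(CN_low = 5e-6), n_genes = 200,
    gene_length_sdlog = 0, fg_median = 3.9, fg_sdlog = 0,
    silent_ratio = 0, seed = 3)
  gen <- generate_cohort(cfg)
  mu_hat <- estimate_background_mu(gen$cohort, n_genes = 200)
  expect_equal(mu_hat, 5e-6, tolerance = 0.1)
})

test_that("estimate_background_mu with gene_params solves the mixed model", {
  cfg <- cohort_config(
    cells = tibble::tibble(stage_class = "early", subgroup = "CN_low", n = 500L),
    mu = c(CN_low = 8e-6), n_genes = 150, silent_ratio = 0, seed = 8)
  gen <- generate_cohort(cfg)   # heterogeneous per-gene f_g and L
  mu_hat <- estimate_background_mu(gen$cohort, n_genes = 150,
                                   gene_params = gen$genes)
  expect_equal(mu_hat, 8e-6, tolerance = 0.15)
})
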