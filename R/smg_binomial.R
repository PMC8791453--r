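#' Binomial background/signal mutation model
#'
#' Parameter container for the binomial model of per-gene mutation counts
#' used to detect significantly mutated genes (SMGs) and to estimate
#' detection power. Under the background (null), the probability that a
#' tumor carries at least one non-silent mutation in a gene is
#' `p0 = 1 - (1 - mu * f_g)^((3/4) * L)`, where `mu` is the per-base
#' background mutation rate per tumor, `f_g` the gene-specific mutation
#' rate factor, and `L` the gene length in bases; `(3/4) * L` approximates
#' the number of positions at which a mutation is non-silent. Under the
#' signal, `p1 = p0 + r * (1 - m)` where `r` is the true fraction of
#' tumors carrying a driver mutation and `m` the mis-detection rate. The
#' defaults `f_g = 3.9` and `L = 1500` are conservative 90th-percentile
#' constants.
#'
#' @param mu Background mutation rate per base per tumor.
#' @param f_g Gene-specific mutation rate factor.
#' @param L Gene length in bases.
#' @param m Mis-detection rate in `[0, 1]`.
#' @param alpha Family significance level.
#' @param k Number of hypotheses tested (the per-test level is `alpha/k`).
#' @return An object of class `background_model`.
#' @export
background_model <- function(mu, f_g = 3.9, L = 1500, m = 0.1,
                             alpha = 0.1, k = 14) {
  stopifnot(length(mu) == 1, mu >= 0, f_g > 0, L > 0,
            m >= 0, m <= 1, alpha > 0, alpha <= 1, k >= 1)
  if (mu * f_g > 1) stop("mu * f_g exceeds 1: not a probability", call. = FALSE)
  structure(list(mu = mu, f_g = f_g, L = L, m = m, alpha = alpha, k = k),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(paste0("<background_model> mu=%.3g f_g=%.3g L=%g m=%.3g ",
                     "alpha=%.3g k=%d (p0=%.4g)\n"),
              x$mu, x$f_g, x$L, x$m, x$alpha, as.integer(x$k),
              background_rate(x)))
  invisible(x)
}

#' Background per-gene mutation probability
#'
#' `p0 = 1 - (1 - mu * f_g)^((3/4) * L)`, evaluated in log space
#' (`log1p`/`expm1`) for numerical stability at small rates.
#'
#' @param model A [background_model()], or a numeric `mu` (then `f_g`, `L`
#'   are taken from the arguments).
#' @param f_g,L Used when `model` is a bare rate.
#' @return Probability in `[0, 1]` that a tumor has at least one
#'   background non-silent mutation in the gene.
#' @export
background_rate <- function(model, f_g = 3.9, L = 1500) {
  if (inherits(model, "background_model")) {
    mu <- model$mu; f_g <- model$f_g; L <- model$L
  } else {
    mu <- model
  }
  if (any(mu * f_g > 1)) stop("mu * f_g exceeds 1", call. = FALSE)
  -expm1(0.75 * L * log1p(-mu * f_g))
}

#' Signal per-gene mutation probability
#'
#' `p1 = min(1, p0 + r * (1 - m))`: the background probability plus the
#' driver mutation frequency discounted by the mis-detection rate.
#'
#' @param p0 Background probability from [background_rate()].
#' @param r Fraction of tumors carrying a driver mutation in the gene.
#' @param m Mis-detection rate.
#' @return Probability in `[p0, 1]`.
#' @export
signal_rate <- function(p0, r, m = 0.1) {
  stopifnot(all(p0 >= 0 & p0 <= 1), all(r >= 0 & r <= 1),
            all(m >= 0 & m <= 1))
  pmin(1, p0 + r * (1 - m))
}

#' Per-gene binomial exceedance p-value
#'
#' One-sided inclusive upper-tail probability
#' `P(X >= x)` for `X ~ Binomial(n, p0)`: the probability of seeing at
#' least the observed number of mutated tumors under the background model.
#' One-sided because only mutation excess defines a driver.
#'
#' @param x Observed number of tumors with at least one non-silent
#'   mutation in the gene.
#' @param n Number of tumors.
#' @param p0 Background per-gene mutation probability.
#' @return P-value vector (1 where `x = 0`).
#' @export
gene_pvalue <- function(x, n, p0) {
  if (any(p0 < 0 | p0 > 1)) stop("p0 outside [0, 1]", call. = FALSE)
  stopifnot(all(x >= 0), all(x <= n))
  stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
}

#' Power to detect a significantly mutated gene
#'
#' Probability, under the signal model, of obtaining a background p-value
#' at or below the per-test level `alpha/k`:
#' `sum over x of dbinom(x; n, p1) * 1[gene_pvalue(x, n, p0) <= alpha/k]`.
#' Computed exactly from binomial tail sums (no simulation).
#'
#' @param n Number of tumors.
#' @param model A [background_model()].
#' @param r Non-silent driver mutation frequency.
#' @return Power in `[0, 1]`.
#' @export
detect_power <- function(n, model, r) {
  stopifnot(inherits(model, "background_model"), n >= 1)
  p0 <- background_rate(model)
  p1 <- signal_rate(p0, r, model$m)
  level <- model$alpha / model$k
  pv <- stats::pbinom((0:n) - 1, n, p0, lower.tail = FALSE)  # P(X >= x)
  hit <- which(pv <= level)
  if (length(hit) == 0) return(0)
  crit <- hit[1] - 1  # smallest x whose p-value reaches the level
  stats::pbinom(crit - 1, n, p1, lower.tail = FALSE)
}

#' Power grid over background rates and mutation frequencies
#'
#' @param n Number of tumors.
#' @param model A [background_model()]; its `mu` is overridden cell-wise.
#' @param mu_values,r_values Grid axes.
#' @return An object of class `power_grid`: list with `mu_values`,
#'   `r_values`, `power` (matrix indexed `[mu, r]`), `n`, and the model
#'   constants. `as.data.frame()` gives the long form.
#' @export
power_grid <- function(n, model, mu_values, r_values) {
  stopifnot(length(mu_values) > 0, length(r_values) > 0)
  power <- matrix(NA_real_, length(mu_values), length(r_values),
                  dimnames = list(signif(mu_values, 4), signif(r_values, 4)))
  for (i in seq_along(mu_values)) {
    mod_i <- background_model(mu_values[i], model$f_g, model$L, model$m,
                              model$alpha, model$k)
    for (j in seq_along(r_values)) {
      power[i, j] <- detect_power(n, mod_i, r_values[j])
    }
  }
  structure(list(mu_values = mu_values, r_values = r_values, power = power,
                 n = n, f_g = model$f_g, L = model$L, m = model$m,
                 alpha = model$alpha, k = model$k),
            class = "power_grid")
}

#' @export
as.data.frame.power_grid <- function(x, ...) {
  grid <- expand.grid(mu = x$mu_values, r = x$r_values)
  grid$power <- as.vector(x$power)
  grid
}

#' Estimate the cohort background mutation rate
#'
#' Inverts the background model from the observed mean per-gene mutated
#' fraction: with `p0_hat` = mutated (gene, sample) pairs divided by
#' `n_samples * n_genes`, returns the `mu` solving
#' `p0_hat = 1 - (1 - mu * f_g)^((3/4) L)`. Driver signal inflates the
#' estimate by at most a few planted genes' worth, negligible for
#' realistic gene universes.
#'
#' @param cohort An `eec_cohort` with coding/splice variants.
#' @param n_genes Size of the gene universe over which mutations could
#'   have been observed (not just the mutated genes); ignored when
#'   `gene_params` is given.
#' @param f_g,L Model constants (used without `gene_params`).
#' @param gene_params Optional tibble with `gene`, `f_g`, `L` giving
#'   gene-specific backgrounds; `mu` is then found by solving
#'   `sum_g p0_g(mu)` = observed mutated (gene, sample) pairs per sample.
#' @return Estimated `mu`.
#' @export
estimate_background_mu <- function(cohort, n_genes, f_g = 3.9, L = 1500,
                                   gene_params = NULL) {
  v <- cohort$variants
  ns <- v[is_nonsilent(v$variant_classification), , drop = FALSE]
  pairs <- nrow(dplyr::distinct(ns, .data$gene, .data$sample_id))
  per_sample <- pairs / nrow(cohort$clinical)
  if (is.null(gene_params)) {
    p0_hat <- per_sample / n_genes
    if (p0_hat >= 1) stop("saturated cohort: cannot invert background model",
                          call. = FALSE)
    return(-expm1(log1p(-p0_hat) / (0.75 * L)) / f_g)
  }
  expected <- function(mu) {
    sum(-expm1(0.75 * gene_params$L *
                 log1p(-pmin(1, mu * gene_params$f_g))))
  }
  upper <- 0.99 / max(gene_params$f_g)
  if (expected(upper) < per_sample) {
    stop("saturated cohort: cannot invert background model", call. = FALSE)
  }
  stats::uniroot(function(mu) expected(mu) - per_sample,
                 lower = 0, upper = upper, tol = 1e-14)$root
}

#' Scan a cohort for significantly mutated genes
#'
#' For each gene with at least one non-silent variant, counts the distinct
#' samples mutated (one sample counts once per gene regardless of how many
#' variants it carries there) and computes the one-sided binomial
#' exceedance p-value against the background model. Q-values and SMG flags
#' are left for [adjust_gene_results()] / [call_smgs()].
#'
#' @param cohort An `eec_cohort` filtered to coding/splice variants.
#' @param model A [background_model()].
#' @param gene_params Optional tibble with `gene`, `f_g`, `L` overriding
#'   the model constants gene by gene (a gene-specific background); genes
#'   absent from the table fall back to the model's constants.
#' @return Tibble with `gene`, `n_tumors`, `n_mutated`, `freq`, `p_value`,
#'   `q_value` (NA), `is_smg` (NA), sorted by `p_value`.
#' @export
smg_scan <- function(cohort, model, gene_params = NULL) {
  stopifnot(inherits(cohort, "eec_cohort"), inherits(model, "background_model"))
  n_tumors <- nrow(cohort$clinical)
  if (n_tumors == 0) stop("empty cohort: no samples", call. = FALSE)
  v <- cohort$variants
  ns <- v[is_nonsilent(v$variant_classification), , drop = FALSE]
  if (nrow(ns) == 0) stop("empty cohort: no non-silent variants", call. = FALSE)
  counts <- dplyr::count(dplyr::distinct(ns, .data$gene, .data$sample_id),
                         .data$gene, name = "n_mutated")
  p0 <- rep(background_rate(model), nrow(counts))
  if (!is.null(gene_params)) {
    idx <- match(counts$gene, gene_params$gene)
    hit <- !is.na(idx)
    p0[hit] <- background_rate(model$mu, f_g = gene_params$f_g[idx[hit]],
                               L = gene_params$L[idx[hit]])
  }
  out <- tibble::tibble(
    gene = counts$gene,
    n_tumors = n_tumors,
    n_mutated = counts$n_mutated,
    freq = counts$n_mutated / n_tumors,
    p_value = gene_pvalue(counts$n_mutated, n_tumors, p0),
    q_value = NA_real_,
    is_smg = NA
  )
  dplyr::arrange(out, .data$p_value, .data$gene)
}
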