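# Independent oracles used to freeze expected values. These deliberately take
# different computational routes from the package code they check.

# Closed-form integral of the 4PL in log10-dose: antiderivative
# F(x) = t*x - (t - b) * log10(1 + 10^(h*(x - e))) / h, evaluated at the bounds.
closed_form_auc <- function(b, t, e, h, lo_nM = 1e-7, hi_nM = 1e3) {
  F <- function(x) {
    # log1p in base 10 for numerical stability at large h*(x - e)
    u <- h * (x - e)
    lt <- ifelse(u > 30, u, log10(1 + 10^u))
    t * x - (t - b) * lt / h
  }
  F(log10(hi_nM)) - F(log10(lo_nM))
}

# Brute-force exact HWE test by direct enumeration with exact factorials
# (valid for n <= 50 since factorial(100) < .Machine$double.xmax).
hwe_brute_force <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  w <- vapply(hs, function(h) {
    n1 <- (nA - h) / 2
    n2 <- (na - h) / 2
    factorial(n) / (factorial(n1) * factorial(h) * factorial(n2)) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  p_obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Analytic power of the two-sided Pearson correlation test via the Fisher-z
# approximation.
fisher_z_power <- function(rho, n, alpha) {
  z <- atanh(rho) * sqrt(n - 3)
  crit <- qnorm(1 - alpha / 2)
  pnorm(z - crit) + pnorm(-z - crit)
}

# Small, fast simulation configuration, unplanted unless overridden.
tiny_config <- function(seed = 1L, planted_effects = NULL, ...) {
  sim_config(
    n_per_population = c(A = 30, B = 30),
    n_snps = 200, n_probes = 100, n_mirna = 40,
    n_mirna_extra_samples = 2, n_fail_mirna_probes = 5,
    n_fail_mirna_samples = 4, n_fail_mirna_sd = 5,
    n_fail_call_rate = 5, n_fail_maf = 5, n_fail_hwe = 5,
    n_low_expr = 10,
    planted_effects = planted_effects, snp_annotation = NULL,
    probe_annotation = NULL,
    seed = seed, ...
  )
}

# Deterministic toy cohort for integration tests: a planted causal chain
# snp -> probe -> phenotype with strong effects plus independent nulls.
toy_triangle_cohort <- function(n = 120, seed = 5) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  g_causal <- rbinom(n, 2, 0.4)
  probe_causal <- 0.9 * scale(g_causal)[, 1] + 0.3 * rnorm(n)
  pheno <- 0.8 * scale(probe_causal)[, 1] + 0.4 * rnorm(n)
  dosage <- cbind(
    snp_causal = g_causal,
    snp_null1 = rbinom(n, 2, 0.3),
    snp_null2 = rbinom(n, 2, 0.5)
  )
  rownames(dosage) <- ids
  storage.mode(dosage) <- "double"
  probes <- cbind(
    probe_causal = probe_causal,
    probe_null1 = rnorm(n),
    probe_null2 = rnorm(n)
  )
  rownames(probes) <- ids
  gm <- genotype_matrix(dosage, tibble::tibble(
    snp_id = colnames(dosage), gene = c("HOSTG", "NULLG1", "NULLG2"),
    func_class = c("upstream", "intron", "intron")))
  em <- expression_matrix(probes, tibble::tibble(
    probe_id = colnames(probes), gene = c("TARGETG", "NULLP1", "NULLP2")))
  list(genotypes = gm, expression = em,
       phenotype = setNames(pheno, ids))
}
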