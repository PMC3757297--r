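test_that("van der Waerden scores match hand-computed normal quantiles", {
  expect_equal(van_der_waerden(c(5, 1, 9)),
               qnorm(c(0.5, 0.25, 0.75)), tolerance = 1e-12)
  # tied pair takes the average rank 1.5
  expect_equal(van_der_waerden(c(2, 2, 7)),
               qnorm(c(1.5 / 4, 1.5 / 4, 3 / 4)), tolerance = 1e-12)
  # invariance under strictly increasing transforms; NA preserved
  x <- c(0.3, -1, 2.2, NA, 0.9, 5)
  expect_identical(van_der_waerden(x), van_der_waerden(exp(x)))
  expect_true(is.na(van_der_waerden(x)[4]))
  expect_equal(van_der_waerden(rep(3, 5)), rep(0, 5))
  expect_error(van_der_waerden(c(1, 2)), "3 non-missing")
})

test_that("covariate adjustment returns exact OLS residuals", {
  set.seed(71)
  n <- 80
  design <- data.frame(sex = rep(c("F", "M"), 40), race = rep(c("a", "b"), each = 40),
                       pc1 = rnorm(n))
  y <- rnorm(n)
  res <- adjust_covariates(y, design, standardize = FALSE)
  X <- model.matrix(~ ., design)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
  std <- adjust_covariates(y, design, standardize = TRUE)
  expect_equal(mean(std), 0, tolerance = 1e-8)
  expect_equal(var(std), 1, tolerance = 1e-8)
  # values spanned by the design leave (near) zero residuals -> degenerate
  y2 <- 2 * (design$sex == "M")
  expect_error(adjust_covariates(y2, design), "degenerate")
  # collinear columns are named in the error
  design$sex2 <- as.numeric(design$sex == "M")
  expect_error(adjust_covariates(y, design), "sex2")
})

test_that("exact HWE p-values match enumeration spot checks", {
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-10)
  expect_equal(hwe_exact_p(1, 0, 0), 1)
  expect_equal(hwe_exact_p(20, 10, 20), hwe_brute_force(20, 10, 20),
               tolerance = 1e-12)
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
  expect_error(hwe_exact_p(-1, 2, 0), "nonnegative")
})

test_that("SNP QC applies strict cutoffs in the fixed attribution order", {
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  mk <- function(...) {
    d <- cbind(...)
    rownames(d) <- ids
    genotype_matrix(d)
  }
  # MAF exactly 0.05: counts AA=90, Aa=10 -> kept by the strict rule;
  # but such a column is far out of HWE... use counts that satisfy both:
  boundary <- c(rep(0, 90), rep(1, 10))
  expect_equal(min(mean(boundary) / 2, 1 - mean(boundary) / 2), 0.05)
  mono <- rep(0, n)
  allhet <- rep(1, n)
  lowcall <- c(rep(NA, 10), rep(c(0, 1, 2, 1), length.out = 90))
  good <- rep(c(0, 1, 2, 1), length.out = n)
  gm <- mk(s_boundary = boundary, s_mono = mono, s_allhet = allhet,
           s_lowcall = lowcall, s_good = good)
  qc <- snp_qc(gm)
  det <- attr(qc$report, "details")
  expect_equal(det$status[det$snp_id == "s_boundary"], "pass")
  expect_equal(det$status[det$snp_id == "s_mono"], "maf")
  expect_equal(det$status[det$snp_id == "s_allhet"], "hwe")
  expect_equal(det$status[det$snp_id == "s_lowcall"], "call_rate")
  expect_equal(det$status[det$snp_id == "s_good"], "pass")
  expect_equal(attr(qc$report, "n_retained") +
                 sum(qc$report$n_removed), attr(qc$report, "n_input"))
  # idempotence: a second pass removes nothing
  qc2 <- snp_qc(qc$genotypes)
  expect_identical(qc2$genotypes$dosage, qc$genotypes$dosage)
  expect_equal(sum(qc2$report$n_removed), 0)
})

test_that("genotype PCs separate simulated populations and respect symmetry", {
  cfg <- sim_config(n_per_population = c(A = 60, B = 60), n_snps = 2000,
                    fst = 0.1, planted_effects = NULL, snp_annotation = NULL,
                    probe_annotation = NULL, n_fail_call_rate = 0,
                    n_fail_maf = 0, n_fail_hwe = 0, seed = 3)
  gm <- snp_qc(simulate_genotypes(cfg))$genotypes
  pcs <- compute_pcs(gm, 4)
  pop <- rep(c(0, 1), c(60, 60))
  expect_gt(abs(cor(pcs$scores$PC1, pop)), 0.9)
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
  # orthonormal sample coordinates
  U <- as.matrix(pcs$scores[, -1])
  expect_equal(unname(crossprod(U)), diag(4), tolerance = 1e-8)
  # column-order invariance up to component sign
  perm <- sample(ncol(gm$dosage))
  gm2 <- genotype_matrix(gm$dosage[, perm], gm$snps[perm, ])
  pcs2 <- compute_pcs(gm2, 4)
  agree <- abs(diag(cor(U, as.matrix(pcs2$scores[, -1]))))
  expect_true(all(agree > 1 - 1e-8))
  expect_error(compute_pcs(gm, 0), "positive")
})

test_that("no dominant PC arises without population structure", {
  cfg <- sim_config(n_per_population = c(ONLY = 120), n_snps = 2000, fst = 0,
                    planted_effects = NULL, snp_annotation = NULL,
                    probe_annotation = NULL, n_fail_call_rate = 0,
                    n_fail_maf = 0, n_fail_hwe = 0, seed = 5)
  gm <- snp_qc(simulate_genotypes(cfg))$genotypes
  pcs <- compute_pcs(gm, 4)
  expect_lt(pcs$eigenvalues[1] / pcs$eigenvalues[2], 2)
})

test_that("microRNA cascade stages fire in order with inclusive cutoffs", {
  n <- 20; m <- 6
  ids <- sprintf("S%02d", 1:n)
  vals <- matrix(rnorm(n * m, 8, 1), n, m,
                 dimnames = list(ids, sprintf("p%d", 1:m)))
  detp <- matrix(0.001, n, m, dimnames = dimnames(vals))
  detp[1:18, 1] <- 0.5                   # probe 1: 90% missing -> stage 1
  vals[, 2] <- 7                          # probe 2: constant -> stage 3
  detp[1, 2:6] <- 0.99                    # sample 1: 100% missing on survivors
  mm <- mirna_matrix(vals, detp)
  out <- mirna_filter_cascade(mm)
  expect_equal(out$report$n_removed, c(1, 1, 1))
  expect_setequal(colnames(out$mirna$values), c("p3", "p4", "p5", "p6"))
  expect_false("S01" %in% rownames(out$mirna$values))
  # an entry at exactly the detection alpha counts as missing (>= rule)
  detp2 <- matrix(0.001, n, m, dimnames = dimnames(vals))
  detp2[1:16, 3] <- 0.01                  # exactly 80% at the threshold
  out2 <- mirna_filter_cascade(mirna_matrix(vals, detp2))
  expect_false("p3" %in% colnames(out2$mirna$values))
})

test_that("low-expression mask uses strict linear-scale boundaries", {
  ids <- sprintf("S%02d", 1:10)
  vals <- cbind(at50 = rep(log2(50), 10), at49 = rep(log2(49), 10),
                mixed = rep(c(4, 8), 5))
  rownames(vals) <- ids
  em <- expression_matrix(vals)
  mask <- low_expression_mask(em)
  expect_false(mask$masked[mask$probe_id == "at50"])   # exactly 50 is kept
  expect_true(mask$masked[mask$probe_id == "at49"])
  # linear-scale averaging: (16 + 256) / 2 = 136 >= 50
  expect_equal(mask$mean_linear[mask$probe_id == "mixed"], 136)
  expect_false(mask$masked[mask$probe_id == "mixed"])
})

test_that("phenotype preprocessing yields standardized design-orthogonal scores", {
  cfg <- tiny_config(seed = 72)
  st <- simulate_study(cfg)
  auc <- derive_auc_phenotypes(
    dplyr::filter(st$dose_response, drug == cfg$drug_names[1]))
  pcs <- compute_pcs(snp_qc(st$genotypes)$genotypes, 2)
  ph <- preprocess_phenotype(auc, st$covariates, pcs)
  expect_equal(mean(ph$adjusted), 0, tolerance = 1e-8)
  expect_equal(var(ph$adjusted), 1, tolerance = 1e-8)
  sex <- as.numeric(st$covariates$sex[match(ph$sample_id,
                                            st$covariates$sample_id)] == "M")
  expect_lt(abs(cor(ph$adjusted, sex)), 1e-8)
  expect_lt(abs(cor(ph$adjusted,
                    pcs$scores$PC1[match(ph$sample_id, pcs$scores$sample_id)])),
            1e-8)
})
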