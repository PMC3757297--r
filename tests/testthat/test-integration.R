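test_that("triangulation recovers a constructed causal chain and only it", {
  toy <- toy_triangle_cohort()
  snp_auc <- pearson_scan(toy$genotypes, toy$phenotype, kind = "snp",
                          qvalues = FALSE)
  expr_auc <- pearson_scan(toy$expression, toy$phenotype, qvalues = FALSE)
  tri <- triangulate(snp_auc, expr_auc, toy$genotypes, toy$expression,
                     drug = "drugX")
  expect_equal(nrow(tri), 1)
  expect_equal(tri$snp_id, "snp_causal")
  expect_equal(tri$probe_id, "probe_causal")
  expect_equal(tri$gene, "TARGETG")
  expect_equal(tri$snp_gene, "HOSTG")
  # break the expression-phenotype leg: permuted probe kills the triangle
  em2 <- toy$expression
  perm <- sample(nrow(em2$values))
  em2$values[, "probe_causal"] <- em2$values[perm, "probe_causal"]
  expr_auc2 <- pearson_scan(em2, toy$phenotype, qvalues = FALSE)
  tri2 <- triangulate(snp_auc, expr_auc2, toy$genotypes, em2)
  expect_equal(nrow(tri2), 0)
  # tighter thresholds always give a subset
  tri3 <- triangulate(snp_auc, expr_auc, toy$genotypes, toy$expression,
                      thresholds = c(1e-6, 1e-6, 1e-5))
  expect_true(all(paste(tri3$snp_id, tri3$probe_id) %in%
                    paste(tri$snp_id, tri$probe_id)))
  # input row order is irrelevant
  tri4 <- triangulate(snp_auc[sample(nrow(snp_auc)), ],
                      expr_auc[sample(nrow(expr_auc)), ],
                      toy$genotypes, toy$expression, drug = "drugX")
  expect_equal(tri4, tri)
  expect_error(triangulate(snp_auc, expr_auc, toy$genotypes, toy$expression,
                           thresholds = c(2, 1e-4, 1e-3)), "thresholds")
})

test_that("cross-drug overlap is an exact keyed intersection", {
  toy <- toy_triangle_cohort()
  snp_auc <- pearson_scan(toy$genotypes, toy$phenotype, kind = "snp",
                          qvalues = FALSE)
  expr_auc <- pearson_scan(toy$expression, toy$phenotype, qvalues = FALSE)
  tri_a <- triangulate(snp_auc, expr_auc, toy$genotypes, toy$expression,
                       drug = "A")
  tri_b <- triangulate(snp_auc, expr_auc, toy$genotypes, toy$expression,
                       drug = "B")
  ov <- overlap_across_drugs(tri_a, tri_b)
  expect_equal(nrow(ov), 1)
  expect_true(all(c("snp_auc_p_a", "snp_auc_p_b") %in% names(ov)))
  expect_equal(nrow(overlap_across_drugs(tri_a, tri_b[0, ])), 0)
})

test_that("each candidate rule fires exactly as specified", {
  # hand-built association tables for two drugs
  mk_expr <- function(p_by_probe) {
    tibble::tibble(feature_id = names(p_by_probe), kind = "probe",
                   n_used = 272L, r = 0.3, p = unname(p_by_probe), q = 0.1)
  }
  mk_snp <- function(p_by_snp) {
    tibble::tibble(feature_id = names(p_by_snp), kind = "snp",
                   n_used = 272L, r = -0.3, p = unname(p_by_snp), q = 0.5)
  }
  expr_assoc <- list(
    rapa = mk_expr(c(pA = 1e-6, pB1 = 3.7e-5, pB2 = 5.8e-5, pC = 2e-5,
                     pLow = 1e-8, pNull = 0.3)),
    ever = mk_expr(c(pA = 5e-5, pB1 = 0.2, pB2 = 0.4, pC = 0.02,
                     pLow = 1e-7, pNull = 0.5))
  )
  snp_assoc <- list(
    rapa = mk_snp(c(s1 = 2e-5, s2 = 8e-5, s3 = 2.77e-5, s4 = 0.2)),
    ever = mk_snp(c(s1 = 5e-5, s2 = 9e-5, s3 = 0.1, s4 = 0.3))
  )
  ids <- sprintf("S%02d", 1:10)
  vals <- cbind(pA = rep(8, 10), pB1 = rep(8, 10), pB2 = rep(8, 10),
                pC = rep(9, 10), pLow = rep(log2(30), 10), pNull = rep(8, 10))
  rownames(vals) <- ids
  em <- expression_matrix(vals, tibble::tibble(
    probe_id = colnames(vals),
    gene = c("GA", "GB", "GB", "GMULTI", "GLOW", "GNULL")))
  snp_meta <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    gene = c("GMULTI", "GMULTI", "GNS", "GX"),
    func_class = c("intron", "intron", "nonsynonymous", "nonsynonymous"))
  cand <- select_candidates(expr_assoc, snp_assoc, triangles = NULL,
                            em = em, snp_meta = snp_meta)
  summ <- summarise_candidates(cand)
  # pA passes in both drugs -> overlap rule; also p < 1e-5 in one drug
  expect_true("overlap_both_drugs" %in% cand$rule[cand$gene == "GA"])
  expect_true("p_lt_1e-5_single_drug" %in% cand$rule[cand$gene == "GA"])
  # GB holds two sub-1e-4 probes for rapamycin only
  expect_true("two_probes_one_gene" %in% cand$rule[cand$gene == "GB"])
  # low-expression gene is excluded despite extreme p
  expect_false("GLOW" %in% cand$gene)
  # GMULTI has two SNPs below 1e-4 in both drugs and is expressed
  expect_true("multi_snp_gene" %in% cand$rule[cand$gene == "GMULTI"])
  # nonsynonymous SNP rule needs p < 1e-4 (s3 rapa only; s4 never passes)
  expect_true("nonsynonymous_snp" %in% cand$rule[cand$gene == "GNS"])
  expect_false("GX" %in% cand$gene)
  expect_false("GNULL" %in% cand$gene)
  expect_setequal(summ$gene, c("GA", "GB", "GMULTI", "GNS"))
  # determinism / idempotence
  cand2 <- select_candidates(expr_assoc, snp_assoc, NULL, em, snp_meta)
  expect_identical(cand, cand2)
  # audit: every expression-panel trigger is re-verifiable from its table
  for (i in which(cand$panel == "expression")) {
    d <- cand$drug[i]
    tbl <- expr_assoc[[d]]
    expect_equal(cand$p[i], tbl$p[tbl$feature_id == cand$feature_id[i]])
    expect_lt(cand$p[i], 1e-4 + 1e-12)
  }
  # manual additions require a justification
  expect_error(select_candidates(expr_assoc, snp_assoc, NULL, em, snp_meta,
                                 manual = tibble::tibble(gene = "GM",
                                                         justification = "")),
               "justification")
  with_manual <- select_candidates(
    expr_assoc, snp_assoc, NULL, em, snp_meta,
    manual = tibble::tibble(gene = "GM", justification = "multi-SNP follow-up"))
  expect_true("manual" %in% with_manual$rule[with_manual$gene == "GM"])
  # missing functional annotation downgrades the rule with a warning
  expect_warning(
    select_candidates(expr_assoc, snp_assoc, NULL, em,
                      snp_meta |> dplyr::select(-func_class)),
    "nonsynonymous")
})

test_that("microRNA screen flags planted signal and reports repression pairs", {
  set.seed(91)
  n <- 262
  ids <- sprintf("S%03d", 1:n)
  s <- rnorm(n)                                   # latent sensitivity proxy
  pheno <- setNames(s, ids)
  u <- 0.4 * s + sqrt(1 - 0.16) * rnorm(n)        # planted microRNA signal
  mir_vals <- cbind(mir_hit = u,
                    matrix(rnorm(n * 39), n,
                           dimnames = list(NULL, sprintf("mir_null%02d", 1:39))))
  rownames(mir_vals) <- ids
  mm <- mirna_matrix(mir_vals, matrix(0.001, n, 40, dimnames = dimnames(mir_vals)))
  probes <- cbind(
    rep1 = -0.3 * s - 0.4 * (u - 0.4 * s) + 0.6 * rnorm(n),  # repressed target
    tgt2 = 0.45 * s + 0.8 * rnorm(n),
    null1 = rnorm(n))
  rownames(probes) <- ids
  em <- expression_matrix(probes, tibble::tibble(
    probe_id = colnames(probes), gene = c("GR1", "GT2", "GN")))
  mirna_assoc <- list(
    rapa = pearson_scan(mm, pheno, kind = "mirna"),
    ever = pearson_scan(mm, pheno, kind = "mirna"))
  expr_assoc <- list(
    rapa = pearson_scan(em, pheno),
    ever = pearson_scan(em, pheno))
  out <- mirna_screen(mirna_assoc, expr_assoc, em, mm)
  expect_equal(out$threshold$threshold, 0.05 / 40)
  flagged <- out$associations |> dplyr::filter(flagged)
  # the planted microRNA is flagged in both drugs and is the top hit; the
  # 5 percent FWER screen may admit at most a stray null
  expect_true(all(c("rapa", "ever") %in% flagged$drug[flagged$feature_id == "mir_hit"]))
  top <- out$associations |> dplyr::group_by(drug) |> dplyr::slice_min(p, n = 1)
  expect_true(all(top$feature_id == "mir_hit"))
  expect_lte(length(setdiff(flagged$feature_id, "mir_hit")), 1)
  expect_true("rep1" %in% out$pairs$probe_id)
  expect_true(all(out$pairs$r[out$pairs$probe_id == "rep1"] < 0))
  expect_false("null1" %in% out$pairs$probe_id)
})
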