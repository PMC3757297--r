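test_that("correlation p-values follow the exact t mapping", {
  # the published miR-10a/Everolimus pair: r = 0.2377 at n = 262
  p <- pgxscan:::pearson_p(0.2377, 262)
  expect_equal(p, 1.04e-4, tolerance = 0.05)
  expect_equal(pgxscan:::pearson_p(0, 100), 1)
  expect_equal(pgxscan:::pearson_p(1, 50), .Machine$double.xmin)
  # strictly decreasing in |r| at fixed n
  rs <- seq(0, 0.99, by = 0.01)
  ps <- pgxscan:::pearson_p(rs, 272)
  expect_true(all(diff(ps) < 0))
  # matches cor.test exactly on a worked example
  set.seed(81)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  ct <- cor.test(x, y)
  expect_equal(pgxscan:::pearson_p(unname(ct$estimate), 40), ct$p.value,
               tolerance = 1e-12)
})

test_that("pearson_scan aligns samples, skips degenerate features, sorts by p", {
  set.seed(82)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  y <- setNames(rnorm(n), ids)
  X <- cbind(strong = y + rnorm(n, 0, 0.3), null = rnorm(n),
             constant = rep(1, n), sparse = c(y[1:3], rep(NA, n - 3)))
  rownames(X) <- ids
  out <- pearson_scan(X, y, kind = "probe")
  expect_equal(out$feature_id[1], "strong")
  expect_false(any(c("constant", "sparse") %in% out$feature_id))
  skipped <- attr(out, "skipped")
  expect_setequal(skipped$feature_id, c("constant", "sparse"))
  expect_true(all(diff(out$p) >= 0))
  expect_true(all(out$q >= 0 & out$q <= 1))
  # q is monotone in p within the table
  expect_true(all(diff(out$q[order(out$p)]) >= -1e-12))
  # pairwise-complete df: feature with some NAs uses its own n
  X2 <- cbind(gap = replace(y + rnorm(n, 0, 0.5), 1:10, NA))
  rownames(X2) <- ids
  out2 <- pearson_scan(X2, y, qvalues = FALSE)
  expect_equal(out2$n_used, n - 10L)
})

test_that("Bonferroni machinery reproduces its arithmetic contracts", {
  bt <- bonferroni_threshold(0.05, 228)
  expect_equal(bt$threshold, 0.05 / 228)
  expect_equal(bt$neg_log10, 3.66)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 54613)$threshold, 9.155e-7,
               tolerance = 1e-4)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(1e-9, 1e6), 1e-3)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("Storey q-values: limits, BH identity and null behaviour", {
  expect_equal(storey_qvalues(rep(1, 20)), rep(1, 20))
  set.seed(83)
  p <- c(runif(900), rbeta(100, 0.2, 5))
  expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
  # uniform nulls: pi0-hat near 1 and q-values large
  p0 <- runif(10000)
  q0 <- storey_qvalues(p0)
  implied_pi0 <- q0[which.max(p0)] / max(p.adjust(p0, "BH")[which.max(p0)], 1e-12)
  expect_gt(implied_pi0, 0.9)
  expect_gt(mean(q0 > 0.5), 0.95)
  o <- order(p0)
  expect_true(all(diff(q0[o]) >= -1e-12))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 2)), "0, 1")
  # fixed-lambda fallback for tiny inputs still yields valid q-values
  q_small <- storey_qvalues(c(0.01, 0.2, 0.8))
  expect_true(all(q_small >= 0 & q_small <= 1))
})

test_that("type-I error and power are calibrated against analytic oracles", {
  set.seed(84)
  n <- 272
  ids <- sprintf("S%03d", 1:n)
  y <- setNames(rnorm(n), ids)
  nulls <- matrix(rnorm(n * 600), n, dimnames = list(ids, sprintf("f%03d", 1:600)))
  scan <- pearson_scan(nulls, y, qvalues = FALSE)
  for (alpha in c(0.05, 0.01)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(scan))
    expect_lt(abs(mean(scan$p < alpha) - alpha), 3 * se)
  }
  # power at alpha = 1e-4 for planted rho = 0.3 vs the Fisher-z oracle;
  # the phenotype is standardized so the planted correlation is exactly rho
  rho <- 0.3
  ys <- setNames(as.numeric(scale(y)), ids)
  planted <- rho * matrix(ys, n, 400) +
    sqrt(1 - rho^2) * matrix(rnorm(n * 400), n)
  dimnames(planted) <- list(ids, sprintf("g%03d", 1:400))
  scan2 <- pearson_scan(planted, ys, qvalues = FALSE)
  emp <- mean(scan2$p < 1e-4)
  expect_lt(abs(emp - fisher_z_power(rho, n, 1e-4)), 0.05)
})
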