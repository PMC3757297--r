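doses8 <- 10^seq(-7, 3, length.out = 8)
curve_tbl <- function(b, t, e, h, doses = doses8, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- logistic_viability(doses, b, t, e, h)
  if (noise > 0) v <- pmax(0, v + rnorm(length(doses), 0, noise))
  tibble::tibble(dose_nM = doses, viability = v)
}

test_that("noiseless curves are recovered to 1e-6 relative error", {
  set.seed(61)
  for (i in 1:10) {
    b <- runif(1, 0, 0.4); t <- runif(1, 0.8, 1.2)
    e <- runif(1, -3, 2); h <- runif(1, 0.5, 3)
    f <- fit_logistic(curve_tbl(b, t, e, h), "FULL_4PL")
    rel <- abs(c(f$bottom - b, f$top - t, f$log10_ic50 - e, f$hill - h)) /
      pmax(abs(c(b, t, e, h)), 1)
    expect_true(all(rel < 1e-6))
    expect_lt(f$rss, 1e-12)
  }
  # fixed-asymptote variants recover their own truths
  ft <- fit_logistic(curve_tbl(0.3, 1, 0.5, 1.5), "TOP_FIXED")
  expect_equal(ft$top, 1)
  expect_lt(abs(ft$bottom - 0.3), 1e-6)
  fb <- fit_logistic(curve_tbl(0, 0.9, 0, 1), "BOTTOM_FIXED")
  expect_equal(fb$bottom, 0)
  expect_lt(abs(fb$top - 0.9), 1e-6)
})

test_that("flat and degenerate inputs follow the documented conventions", {
  flat1 <- tibble::tibble(dose_nM = doses8, viability = rep(1, 8))
  ft <- fit_logistic(flat1, "TOP_FIXED")
  expect_lt(abs(ft$bottom - 1), 1e-6)
  expect_lt(ft$rss, 1e-12)
  fd <- fit_logistic(tibble::tibble(dose_nM = doses8, viability = rep(0.7, 8)),
                     "FULL_4PL")
  expect_true(fd$degenerate)
  expect_equal(fd$bottom, 0.7)
  expect_equal(fd$top, 0.7)
  expect_equal(fd$hill, 0)
  expect_equal(fd$rss, 0)
})

test_that("fit contracts: dose count, positivity, tidy/glance accessors", {
  few <- tibble::tibble(dose_nM = c(1, 10, 100), viability = c(1, 0.6, 0.2))
  expect_error(fit_logistic(few, "FULL_4PL"), "distinct doses")
  expect_error(fit_logistic(tibble::tibble(dose_nM = c(-1, 1, 10, 100),
                                           viability = rep(1, 4))), "positive")
  f <- fit_logistic(curve_tbl(0, 1, 0, 1))
  td <- tidy(f)
  expect_equal(td$term, c("bottom", "top", "log10_ic50", "hill"))
  expect_false(any(td$fixed))
  gl <- glance(f)
  expect_equal(gl$n_params, 4L)
  expect_true(gl$converged)
})

test_that("noisy log-IC50 recovery stays within 0.25 log units (median)", {
  set.seed(62)
  errs <- replicate(100, {
    d <- curve_tbl(0.2, 1, 1, 1.2, noise = 0.05)
    f <- select_best_fit(d)
    abs(f$log10_ic50 - 1)
  })
  expect_lt(median(errs), 0.25)
})

test_that("model selection picks the generating variant and honors ties", {
  set.seed(63)
  picks <- replicate(100, {
    d <- curve_tbl(0.3, 1, 0.5, 1.5, noise = 0.02)
    select_best_fit(d)$variant
  })
  expect_gte(mean(picks == "TOP_FIXED"), 0.90)
  # a free top strictly below 1 forces the full variant on noiseless data
  expect_equal(select_best_fit(curve_tbl(0.1, 0.9, 0, 1))$variant, "FULL_4PL")
  # flat data: all variants fit exactly, 3-parameter member wins the tie
  flat <- tibble::tibble(dose_nM = doses8, viability = rep(1, 8))
  expect_equal(select_best_fit(flat)$variant, "TOP_FIXED")
})

test_that("numerical AUC matches the closed form and is grid-stable", {
  set.seed(64)
  for (i in 1:25) {
    b <- runif(1, 0, 0.5); t <- runif(1, 0.7, 1.2)
    e <- runif(1, -6, 2.5); h <- runif(1, 0.3, 2.5)
    f <- fit_logistic(curve_tbl(b, t, e, h))
    a1 <- compute_auc(f)$auc
    expect_lt(abs(a1 - closed_form_auc(f$bottom, f$top, f$log10_ic50, f$hill)),
              1e-4)
    a2 <- compute_auc(f, n_grid = 8002)$auc
    expect_lt(abs(a1 - a2), 1e-6)
    expect_gte(a1, min(f$bottom, f$top) * 10 - 1e-9)
    expect_lte(a1, max(f$bottom, f$top) * 10 + 1e-9)
  }
})

test_that("AUC limiting cases and monotonicity", {
  flat <- fit_logistic(tibble::tibble(dose_nM = doses8, viability = rep(1, 8)),
                       "TOP_FIXED")
  expect_equal(compute_auc(flat)$auc, 10, tolerance = 1e-9)
  # near-step curve at e = 0: unit viability over [-7, 0], zero over [0, 3]
  step <- structure(list(bottom = 0, top = 1, log10_ic50 = 0, hill = 40,
                         degenerate = FALSE, sample_id = NA, drug = NA,
                         variant = "FULL_4PL", converged = TRUE),
                    class = "logistic_fit")
  expect_equal(compute_auc(step)$auc, 7, tolerance = 0.01)
  # AUC increases with the lower asymptote and with the IC50 location
  auc_at <- function(b, e) {
    closed <- fit_logistic(curve_tbl(b, 1, e, 1.2))
    compute_auc(closed)$auc
  }
  expect_true(auc_at(0.1, 0) < auc_at(0.3, 0))
  expect_true(auc_at(0.1, 0) < auc_at(0.1, 1))
  expect_error(compute_auc(flat, lo_nM = 10, hi_nM = 1), "lo_nM")
})

test_that("phenotype derivation averages replicates and isolates failures", {
  dd <- tidyr::expand_grid(sample_id = c("S1", "S2"), drug = "drugX",
                           dose_nM = doses8, replicate = 1:2)
  dd$viability <- logistic_viability(dd$dose_nM, 0.2, 1, 0.5, 1.2) +
    ifelse(dd$replicate == 1, 0.02, -0.02)
  # S3 has only 3 distinct doses and must fail without harming the others
  bad <- tibble::tibble(sample_id = "S3", drug = "drugX",
                        dose_nM = rep(c(1, 10, 100), 2),
                        replicate = rep(1:2, each = 3), viability = 0.5)
  out <- derive_auc_phenotypes(dplyr::bind_rows(dd, bad))
  expect_setequal(out$sample_id, c("S1", "S2"))
  fails <- attr(out, "failures")
  expect_equal(fails$sample_id, "S3")
  # replicate-averaged fit equals the fit of the mean curve
  avg <- dd |>
    dplyr::filter(sample_id == "S1") |>
    dplyr::group_by(dose_nM) |>
    dplyr::summarise(viability = mean(viability))
  ref <- compute_auc(select_best_fit(avg))$auc
  expect_equal(out$auc[out$sample_id == "S1"], ref, tolerance = 1e-8)
  expect_error(derive_auc_phenotypes(dd[0, ]), "empty")
})
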