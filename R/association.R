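#' Genome-wide Pearson correlation scan
#'
#' Correlates every feature column against a phenotype vector on
#' pairwise-complete observations. Two-sided p-values come from the exact
#' monotone transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t
#' distribution with `n - 2` degrees of freedom; underflowing p-values are
#' floored at the smallest representable positive double. Storey q-values are
#' appended per scan. Features with fewer than `min_n` pairwise-complete
#' observations or zero variance are skipped and reported in the `"skipped"`
#' attribute.
#'
#' @param features samples x features numeric matrix, or a
#'   [genotype_matrix()] / [expression_matrix()] / [mirna_matrix()].
#' @param phenotype named numeric vector (names = sample ids) or tibble with
#'   `sample_id` and a value column (`adjusted` preferred, else `value`).
#' @param kind feature kind label (`"snp"`, `"probe"`, `"mirna"`).
#' @param min_n minimum pairwise-complete observations (default 5).
#' @param qvalues append Storey q-values (default TRUE).
#' @return tibble `feature_id`, `kind`, `n_used`, `r`, `p`, `q`, sorted by `p`,
#'   with skipped features in `attr(., "skipped")`.
#' @export
pearson_scan <- function(features, phenotype, kind = "probe", min_n = 5,
                         qvalues = TRUE) {
  X <- feature_values(features)
  y <- phenotype_vector(phenotype)
  common <- intersect(rownames(X), names(y))
  if (length(common) < min_n) abort("too few shared samples between features and phenotype")
  X <- X[common, , drop = FALSE]
  y <- y[common]

  ok_y <- !is.na(y)
  stats_list <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    use <- ok_y & !is.na(x)
    n <- sum(use)
    if (n < min_n) return(c(n, NA_real_))
    sx <- sd(x[use])
    if (!is.finite(sx) || sx == 0) return(c(n, NA_real_))
    c(n, cor(x[use], y[use]))
  }, numeric(2))
  n_used <- as.integer(stats_list[1, ])
  r <- stats_list[2, ]

  out <- tibble(feature_id = colnames(X), kind = kind, n_used = n_used, r = r)
  skipped <- out |>
    filter(is.na(r)) |>
    mutate(reason = ifelse(n_used < min_n, "too few pairwise-complete samples",
                           "zero-variance feature")) |>
    select(feature_id, n_used, reason)
  out <- out |> filter(!is.na(r))
  out$p <- pearson_p(out$r, out$n_used)
  out$q <- if (qvalues && nrow(out) > 0) storey_qvalues(out$p) else NA_real_
  out <- arrange(out, p)
  attr(out, "skipped") <- skipped
  out
}

# exact two-sided p for a Pearson correlation at df = n - 2, computed in a
# numerically safe way (|r| = 1 maps to the underflow floor, r = 0 to 1)
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tval <- suppressWarnings(r * sqrt(n - 2) / sqrt(1 - r^2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[is.infinite(tval)] <- 0
  pmax(p, .Machine$double.xmin)
}

phenotype_vector <- function(phenotype) {
  if (is.numeric(phenotype) && !is.null(names(phenotype))) return(phenotype)
  if (is.data.frame(phenotype)) {
    col <- intersect(c("adjusted", "value", "auc"), names(phenotype))[1]
    if (is.na(col) || !"sample_id" %in% names(phenotype)) {
      abort("phenotype tibble needs `sample_id` and one of `adjusted`/`value`/`auc`")
    }
    return(setNames(phenotype[[col]], phenotype$sample_id))
  }
  abort("phenotype must be a named numeric vector or a tibble")
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (in (0, 1)).
#' @param m number of tests (>= 1).
#' @return list with `threshold` (`alpha / m`) and `neg_log10` (the threshold
#'   on the -log10 scale, rounded to 2 decimals for display).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (m < 1) abort("`m` must be at least 1")
  thr <- alpha / m
  list(threshold = thr, neg_log10 = round(-log10(thr), 2))
}

#' Bonferroni-adjusted p-value
#'
#' @param p unadjusted p-value(s).
#' @param m number of tests.
#' @return `min(1, p * m)`, vectorized.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (m < 1) abort("`m` must be at least 1")
  pmin(1, p * m)
}

#' Storey false-discovery-rate q-values
#'
#' Estimates the null proportion `pi0` from the p-value histogram:
#' `pi0(lambda) = #{p > lambda} / (m * (1 - lambda))` on
#' `lambda = 0, 0.05, ..., 0.90`, smoothed with a natural cubic smoothing
#' spline (df = 3) and evaluated at `lambda = 0.90`, clamped to (0, 1]. For
#' fewer than 10 p-values the fixed-`lambda = 0.5` estimate is used instead.
#' Q-values are the step-up minima `q(p_(i)) = min_(j >= i) pi0 * m * p_(j) / j`;
#' with `pi0 = 1` they coincide with Benjamini-Hochberg adjusted p-values.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values in the input order (monotone nondecreasing in p).
#' @export
storey_qvalues <- function(pvalues, pi0 = NULL) {
  if (length(pvalues) == 0) abort("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing entries")
  }
  m <- length(pvalues)
  if (is.null(pi0)) {
    if (m < 10) {
      lam <- 0.5
      pi0 <- sum(pvalues > lam) / (m * (1 - lam))
    } else {
      lam <- seq(0, 0.90, by = 0.05)
      pi0_lam <- vapply(lam, function(l) sum(pvalues > l) / (m * (1 - l)), numeric(1))
      fit <- smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- predict(fit, x = 0.90)$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) abort("`pi0` must lie in (0, 1]")
  }
  o <- order(pvalues)
  q_sorted <- pi0 * m * pvalues[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
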