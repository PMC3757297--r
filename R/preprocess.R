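#' Van der Waerden rank-normal scores
#'
#' Maps values to normal quantiles `qnorm(rank / (n + 1))` using average ranks
#' over non-missing entries; missing entries stay missing. The output is
#' invariant under any strictly increasing transform of the input; all-tied
#' inputs map to all-zero scores.
#'
#' @param values numeric vector with at least 3 non-missing entries.
#' @return numeric vector of normal scores.
#' @export
van_der_waerden <- function(values) {
  n <- sum(!is.na(values))
  if (n < 3) abort("need at least 3 non-missing values")
  r <- rank(values, ties.method = "average", na.last = "keep")
  qnorm(r / (n + 1))
}

#' Residualize a vector on a covariate design
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' supplied covariates (categorical columns are one-hot encoded dropping one
#' level), optionally standardized to mean 0 / variance 1. Missing values
#' propagate; design rows for non-missing values must be complete.
#'
#' @param values numeric vector.
#' @param design data frame of covariates (factors/characters and numerics,
#'   e.g. sex, race, batch, principal components), rows aligned with `values`.
#' @param standardize scale residuals to unit variance (default TRUE).
#' @return numeric residual vector.
#' @export
adjust_covariates <- function(values, design, standardize = TRUE) {
  design <- as.data.frame(design, stringsAsFactors = TRUE)
  if (nrow(design) != length(values)) abort("design rows must match values")
  design[] <- lapply(design, function(col) if (is.character(col)) factor(col) else col)
  X <- stats::model.matrix(~ ., data = design)
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (sum(ok) <= ncol(X)) abort("too few non-missing values for the design")
  out[ok] <- lm.fit(X[ok, , drop = FALSE], values[ok])$residuals
  if (standardize) {
    s <- sd(out[ok])
    if (!is.finite(s) || s < 1e-10) {
      abort("degenerate residuals: (near) zero variance after adjustment")
    }
    out[ok] <- (out[ok] - mean(out[ok])) / s
  }
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value sums
#' the probabilities of all heterozygote configurations no more probable than
#' the observed one (same allele-count parity).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, positive total).
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(h | allele counts) up to a constant: multinomial x 2^h
  lp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + hs * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

#' SNP quality control
#'
#' Removes SNPs failing call rate, minor allele frequency or Hardy-Weinberg
#' equilibrium, each with strict-inequality semantics (a SNP exactly at a
#' cutoff is kept). MAF is computed on non-missing genotypes; HWE uses the
#' exact conditional test on genotype counts pooled across samples. A SNP is
#' attributed to the first filter it fails in the fixed order
#' call rate -> MAF -> HWE.
#'
#' @param gm a [genotype_matrix()].
#' @param call_rate_min minimum call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE exact p-value (default 0.001).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (tibble `filter`, `n_removed` with attributes `n_input`, `n_retained`,
#'   and a per-SNP `details` tibble).
#' @export
snp_qc <- function(gm, call_rate_min = 0.95, maf_min = 0.05, hwe_p_min = 0.001) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  status <- rep("pass", ncol(d))
  status[hwe_p < hwe_p_min] <- "hwe"
  status[maf < maf_min] <- "maf"
  status[call_rate < call_rate_min] <- "call_rate"
  details <- tibble(snp_id = colnames(d), call_rate = call_rate, maf = maf,
                    hwe_p = hwe_p, status = status)
  keep <- status == "pass"
  report <- tibble(
    filter = c("call_rate", "maf", "hwe"),
    n_removed = c(sum(status == "call_rate"), sum(status == "maf"),
                  sum(status == "hwe"))
  )
  attr(report, "n_input") <- ncol(d)
  attr(report, "n_retained") <- sum(keep)
  attr(report, "details") <- details
  out <- genotype_matrix(d[, keep, drop = FALSE], gm$snps[keep, ])
  list(genotypes = out, report = report)
}

#' Principal components of standardized genotypes
#'
#' Population-stratification axes in the EIGENSTRAT style: each SNP column is
#' standardized as `(g - 2*p) / sqrt(2*p*(1-p))` with `p` the sample allele
#' frequency, missing entries set to 0 after standardization (mean
#' imputation), and the top `k` left singular vectors over samples returned.
#'
#' @param gm a QC-passed [genotype_matrix()].
#' @param k number of components (positive, below `min(n_samples, n_snps)`).
#' @return list of class `pc_result`: `scores` (tibble `sample_id`,
#'   `PC1`..`PCk`, orthonormal columns) and `eigenvalues` (squared singular
#'   values, nonincreasing).
#' @export
compute_pcs <- function(gm, k = 4) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k <= 0) abort("`k` must be positive")
  d <- gm$dosage
  if (k >= min(dim(d))) abort("`k` must be below min(n_samples, n_snps)")
  p <- colMeans(d, na.rm = TRUE) / 2
  denom <- sqrt(2 * p * (1 - p))
  X <- sweep(d, 2, 2 * p, `-`)
  X <- sweep(X, 2, denom, `/`)
  X[is.na(X)] <- 0
  X[, denom == 0] <- 0
  sv <- svd(X, nu = k, nv = 0)
  scores <- as_tibble(setNames(as.data.frame(sv$u[, seq_len(k), drop = FALSE]),
                               paste0("PC", seq_len(k))))
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(d)), scores)
  structure(list(scores = scores, eigenvalues = sv$d^2), class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  k <- ncol(x$scores) - 1
  cat("<pc_result> ", nrow(x$scores), " samples x ", k, " components; top eigenvalues: ",
      paste(signif(head(x$eigenvalues, k), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' MicroRNA filter cascade
#'
#' Three fixed-order stages on a detection-aware microRNA matrix. An entry is
#' missing when its detection p-value is at or above `det_alpha`. Stage 1
#' removes probes whose missing fraction is at or above `probe_missing_max`;
#' stage 2 removes samples whose missing fraction over the surviving probes is
#' at or above `sample_missing_max`; stage 3 removes probes whose SD of
#' non-missing values over the surviving samples is below `sd_min`. Undetected
#' entries are set to `NA` in the returned matrix.
#'
#' @param mm a [mirna_matrix()].
#' @param det_alpha detection p-value threshold (default 0.01).
#' @param probe_missing_max probe missingness cutoff (default 0.80, inclusive).
#' @param sample_missing_max sample missingness cutoff (default 0.50, inclusive).
#' @param sd_min minimum probe SD (default 0.40, strict).
#' @return list with `mirna` (filtered [mirna_matrix()], undetected entries
#'   `NA`) and `report` (tibble `stage`, `n_removed` with attributes
#'   `n_probes_input`, `n_probes_retained`, `n_samples_input`,
#'   `n_samples_retained`).
#' @export
mirna_filter_cascade <- function(mm, det_alpha = 0.01, probe_missing_max = 0.80,
                                 sample_missing_max = 0.50, sd_min = 0.40) {
  stopifnot(inherits(mm, "mirna_matrix"))
  miss <- mm$detection_p >= det_alpha
  probe_keep1 <- colMeans(miss) < probe_missing_max
  miss2 <- miss[, probe_keep1, drop = FALSE]
  sample_keep <- rowMeans(miss2) < sample_missing_max
  vals <- mm$values[sample_keep, probe_keep1, drop = FALSE]
  vals[miss2[sample_keep, , drop = FALSE]] <- NA_real_
  sds <- apply(vals, 2, sd, na.rm = TRUE)
  probe_keep3 <- !is.na(sds) & sds >= sd_min
  out <- mirna_matrix(
    vals[, probe_keep3, drop = FALSE],
    mm$detection_p[sample_keep, probe_keep1, drop = FALSE][, probe_keep3, drop = FALSE],
    mm$probes[probe_keep1, ][probe_keep3, ]
  )
  report <- tibble(
    stage = c("detection_probes", "missing_samples", "low_sd_probes"),
    n_removed = c(sum(!probe_keep1), sum(!sample_keep), sum(!probe_keep3))
  )
  attr(report, "n_probes_input") <- ncol(mm$values)
  attr(report, "n_probes_retained") <- sum(probe_keep3)
  attr(report, "n_samples_input") <- nrow(mm$values)
  attr(report, "n_samples_retained") <- sum(sample_keep)
  list(mirna = out, report = report)
}

#' Flag probes with low linear-scale expression
#'
#' A probe is masked (excluded from candidacy) when its mean expression on the
#' linear scale, `mean(2^log2_value)`, is strictly below `linear_threshold`.
#'
#' @param em an [expression_matrix()] on the log2 scale (raw, not residualized).
#' @param linear_threshold linear-scale cutoff (default 50).
#' @return tibble `probe_id`, `gene` (if annotated), `mean_linear`, `masked`.
#' @export
low_expression_mask <- function(em, linear_threshold = 50) {
  stopifnot(inherits(em, "expression_matrix"))
  mean_linear <- unname(colMeans(2^em$values))
  # strict "below threshold" with a relative guard so a probe sitting exactly
  # at the cutoff survives log2 round-tripping
  out <- tibble(probe_id = colnames(em$values), mean_linear = mean_linear,
                masked = mean_linear < linear_threshold * (1 - 1e-12))
  if ("gene" %in% names(em$probes)) {
    out <- left_join(out, em$probes[c("probe_id", "gene")], by = "probe_id") |>
      select(probe_id, gene, mean_linear, masked)
  }
  out
}

#' Phenotype preprocessing: rank-normalize, adjust, standardize
#'
#' Applies the phenotype pipeline in its fixed order: van der Waerden
#' transform, then residualization on sex, race and (optionally) the top
#' stratification principal components, then standardization.
#'
#' @param auc tibble with `sample_id` and `auc` (one drug).
#' @param covariates tibble with `sample_id`, `sex`, `race`.
#' @param pcs optional `pc_result` or tibble with `sample_id` and PC columns.
#' @return tibble `sample_id`, `raw`, `vdw`, `adjusted`.
#' @export
preprocess_phenotype <- function(auc, covariates, pcs = NULL) {
  stopifnot(all(c("sample_id", "auc") %in% names(auc)))
  design <- covariates[match(auc$sample_id, covariates$sample_id),
                       c("sex", "race"), drop = FALSE]
  if (anyNA(design$sex)) abort("covariates missing for some phenotype samples")
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_result")) pcs$scores else as_tibble(pcs)
    pccols <- sc[match(auc$sample_id, sc$sample_id),
                 setdiff(names(sc), "sample_id"), drop = FALSE]
    design <- dplyr::bind_cols(design, pccols)
  }
  vdw <- van_der_waerden(auc$auc)
  adjusted <- adjust_covariates(vdw, design, standardize = TRUE)
  tibble(sample_id = auc$sample_id, raw = auc$auc, vdw = vdw, adjusted = adjusted)
}

#' Expression preprocessing: residualize on gender, race and batch
#'
#' Residualizes each log2 probe on sex, race and batch and standardizes the
#' residuals, returning an adjusted [expression_matrix()].
#'
#' @param em an [expression_matrix()] (log2 scale).
#' @param covariates tibble with `sample_id`, `sex`, `race`, `batch`.
#' @return adjusted [expression_matrix()].
#' @export
preprocess_expression <- function(em, covariates) {
  stopifnot(inherits(em, "expression_matrix"))
  ids <- rownames(em$values)
  cov <- covariates[match(ids, covariates$sample_id), c("sex", "race", "batch")]
  if (anyNA(cov$sex)) abort("covariates missing for some expression samples")
  cov[] <- lapply(cov, factor)
  X <- stats::model.matrix(~ ., data = cov)
  res <- lm.fit(X, em$values)$residuals
  res <- scale(res)
  dimnames(res) <- dimnames(em$values)
  expression_matrix(res, em$probes)
}

#' MicroRNA preprocessing: rank-normalize then adjust
#'
#' Per probe: van der Waerden transform of the (cascade-filtered) intensities,
#' then residualization on sex, race and batch and standardization, matching
#' the expression adjustment. Samples without covariates (e.g. assayed outside
#' the cohort) must be removed by the cascade beforehand.
#'
#' @param mm a filtered [mirna_matrix()] (undetected entries `NA`).
#' @param covariates tibble with `sample_id`, `sex`, `race`, `batch`.
#' @return adjusted [mirna_matrix()] (detection p-values carried through).
#' @export
preprocess_mirna <- function(mm, covariates) {
  stopifnot(inherits(mm, "mirna_matrix"))
  ids <- rownames(mm$values)
  cov <- covariates[match(ids, covariates$sample_id), c("sex", "race", "batch")]
  if (anyNA(cov$sex)) abort("covariates missing for some microRNA samples")
  adj <- apply(mm$values, 2, function(v) {
    out <- van_der_waerden(v)
    adjust_covariates(out, cov, standardize = TRUE)
  })
  dimnames(adj) <- dimnames(mm$values)
  mirna_matrix(adj, mm$detection_p, mm$probes)
}
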