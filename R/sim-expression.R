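#' Simulate a log2-scale mRNA expression matrix
#'
#' Baseline log2 abundances are Normal per probe with means drawn from
#' U(6, 12) (linear scale ~64-4096) and a trailing tranche of `n_low_expr`
#' probes drawn from U(3, 5) (linear 8-32) to exercise the low-expression
#' candidate filter. Additive per-probe sex, race and batch coefficients put
#' removable technical/demographic structure on the log2 scale. Planted
#' `probe_auc`, `snp_probe` and `mirna_probe` effects are injected as
#' correlation-targeted mixtures of the latent sensitivity and the driver
#' feature (standardized dosage, or microRNA latent signal).
#'
#' @param genotypes a [genotype_matrix()] (drivers for `snp_probe` effects).
#' @param config a [sim_config()].
#' @param covariates tibble from [simulate_covariates()]; regenerated from the
#'   seed when omitted.
#' @param truth a `planted_truth`; regenerated from the seed when omitted.
#' @return list with `expression` (an [expression_matrix()]) and `truth`.
#' @export
simulate_expression <- function(genotypes, config, covariates = NULL, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  if (is.null(truth)) truth <- simulate_truth(config, genotypes)
  set.seed(sim_seed(config, "expression"))
  n <- sum(config$n_per_population)
  p <- config$n_probes
  ids <- sample_ids(config)
  pids <- probe_ids(p)

  mu <- runif(p, 6, 12)
  if (config$n_low_expr > 0) {
    if (config$n_low_expr >= p) abort("`n_low_expr` must be below `n_probes`")
    mu[(p - config$n_low_expr + 1):p] <- runif(config$n_low_expr, 3, 5)
  }
  sd_p <- runif(p, 0.6, 1.2)
  z <- matrix(rnorm(n * p), nrow = n, dimnames = list(ids, pids))

  # per-probe additive covariate structure (removed later by residualization)
  races <- unique(covariates$race)
  batches <- sort(unique(covariates$batch))
  beta_sex <- rnorm(p, 0, config$sex_sd)
  beta_race <- matrix(rnorm(p * length(races), 0, config$race_sd), nrow = p,
                      dimnames = list(NULL, races))
  beta_batch <- matrix(rnorm(p * length(batches), 0, config$batch_sd), nrow = p,
                       dimnames = list(NULL, batches))

  s_std <- as.numeric(scale(truth$latent$shared))
  eff <- truth$effects
  planted <- unique(c(eff$source[eff$kind == "probe_auc"],
                      eff$target[eff$kind %in% c("snp_probe", "mirna_probe")]))
  for (pid in planted) {
    r_s <- 0
    row_s <- eff[eff$kind == "probe_auc" & eff$source == pid, ]
    if (nrow(row_s)) r_s <- row_s$effect_size[1]
    drv <- eff[eff$kind %in% c("snp_probe", "mirna_probe") & eff$target == pid, ]
    if (nrow(drv) > 1) abort("at most one driver effect per probe is supported")
    driver_std <- NULL
    r_d <- 0
    if (nrow(drv) == 1) {
      r_d <- drv$effect_size[1]
      if (drv$kind == "snp_probe") {
        g <- genotypes$dosage[ids, drv$source]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        driver_std <- as.numeric(scale(g))
      } else {
        if (is.null(truth$mirna_latent) || !drv$source %in% colnames(truth$mirna_latent)) {
          abort(paste0("no microRNA latent signal for ", drv$source))
        }
        driver_std <- as.numeric(scale(truth$mirna_latent[ids, drv$source]))
      }
    }
    z[, pid] <- plant_feature(z[, pid], s_std, r_s, driver_std, r_d)
  }

  values <- sweep(sweep(z, 2, sd_p, `*`), 2, mu, `+`)
  sex_ind <- as.numeric(covariates$sex == "M")
  values <- values + outer(sex_ind, beta_sex)
  values <- values + t(beta_race[, covariates$race, drop = FALSE])
  values <- values + t(beta_batch[, covariates$batch, drop = FALSE])

  probes <- annotate_probes(config)
  list(expression = expression_matrix(values, probes), truth = truth)
}

annotate_probes <- function(config) {
  p <- config$n_probes
  ids <- probe_ids(p)
  # ~10% of null genes carry two probes, like real array designs
  gene <- sprintf("PGEN%04d", ceiling(seq_len(p) / 1.1))
  probes <- tibble(probe_id = ids, gene = gene)
  pin <- config$probe_annotation
  if (!is.null(pin) && nrow(pin)) {
    i <- match(pin$probe_id, probes$probe_id)
    ok <- !is.na(i)
    probes$gene[i[ok]] <- pin$gene[ok]
  }
  probes
}
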