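#' Simulate a bead-array microRNA matrix with detection p-values
#'
#' Emits raw-scale intensities for every microRNA-assayed sample (the cohort
#' plus `n_mirna_extra_samples` non-cohort samples) along with a per-entry
#' detection p-value. Well-measured entries receive detection p below 0.01;
#' a small background fraction (2 percent) is undetected, mimicking bead-level
#' dropouts. Three deliberate tranches feed the downstream filter cascade:
#' probes with 90 percent undetected entries, samples with 60 percent
#' undetected entries, and probes generated with SD ~0.15 (below the 0.40
#' variability cutoff). Planted `mirna_auc`/`mirna_probe` signals are injected
#' from the shared `planted_truth` so microRNA, expression and phenotype stay
#' mutually consistent.
#'
#' @param config a [sim_config()].
#' @param covariates tibble from [simulate_covariates()] (cohort samples);
#'   regenerated from the seed when omitted.
#' @param truth a `planted_truth`; regenerated from the seed when omitted
#'   (standalone use without genotypes skips `snp_auc` latent contributions).
#' @return list with `mirna` (a [mirna_matrix()] whose probe metadata carries
#'   the generator's `violation` label) and `truth`.
#' @export
simulate_mirna <- function(config, covariates = NULL, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  if (is.null(truth)) truth <- simulate_truth(config)
  set.seed(sim_seed(config, "mirna"))

  m <- config$n_mirna
  cohort <- sample_ids(config)
  extras <- if (config$n_mirna_extra_samples > 0) {
    sprintf("EXT%03d", seq_len(config$n_mirna_extra_samples))
  } else character(0)
  ids <- c(cohort, extras)
  n <- length(ids)
  pids <- mirna_ids(m)

  violation <- rep("none", m)
  if (config$n_fail_mirna_probes > 0) {
    violation[(m - config$n_fail_mirna_probes + 1):m] <- "detection"
  }
  if (config$n_fail_mirna_sd > 0) {
    i0 <- m - config$n_fail_mirna_probes - config$n_fail_mirna_sd
    violation[(i0 + 1):(m - config$n_fail_mirna_probes)] <- "sd"
  }
  planted <- if (is.null(truth$mirna_latent)) character(0) else colnames(truth$mirna_latent)
  if (any(planted %in% pids[violation != "none"])) {
    abort("planted microRNAs fall inside a failure tranche; enlarge `n_mirna`")
  }

  # failing samples: all extras plus deterministic draw from the cohort
  n_fail_cohort <- config$n_fail_mirna_samples - length(extras)
  fail_samples <- c(extras,
                    if (n_fail_cohort > 0) sample(cohort, n_fail_cohort) else character(0))

  mu <- runif(m, 6, 10)
  sd_m <- runif(m, 0.6, 1.5)
  sd_m[violation == "sd"] <- 0.15
  z <- matrix(rnorm(n * m), nrow = n, dimnames = list(ids, pids))
  for (pid in planted) {
    u <- c(truth$mirna_latent[cohort, pid], rnorm(length(extras)))
    z[, pid] <- u
  }
  values <- sweep(sweep(z, 2, sd_m, `*`), 2, mu, `+`)

  # additive covariate structure on cohort rows (extras get none; they are
  # removed by the cascade before any modelling)
  races <- unique(covariates$race)
  batches <- sort(unique(covariates$batch))
  # effect magnitudes scale with the probe baseline SD, so low-variability
  # probes stay low-variability
  beta_sex <- rnorm(m, 0, config$sex_sd) * sd_m
  beta_race <- matrix(rnorm(m * length(races), 0, config$race_sd), nrow = m,
                      dimnames = list(NULL, races)) * sd_m
  beta_batch <- matrix(rnorm(m * length(batches), 0, config$batch_sd), nrow = m,
                       dimnames = list(NULL, batches)) * sd_m
  crow <- match(cohort, covariates$sample_id)
  sex_ind <- as.numeric(covariates$sex[crow] == "M")
  values[cohort, ] <- values[cohort, ] + outer(sex_ind, beta_sex) +
    t(beta_race[, covariates$race[crow], drop = FALSE]) +
    t(beta_batch[, covariates$batch[crow], drop = FALSE])

  # detection p-values: detected ~ U(0, 0.005), undetected ~ U(0.01, 1)
  p_undet <- matrix(0.02, nrow = n, ncol = m)
  p_undet[, violation == "detection"] <- 0.90
  p_undet[ids %in% fail_samples, violation != "detection"] <- 0.60
  undetected <- matrix(runif(n * m), nrow = n) < p_undet
  detection_p <- matrix(runif(n * m, 0, 0.005), nrow = n,
                        dimnames = list(ids, pids))
  detection_p[undetected] <- runif(sum(undetected), 0.01, 1)

  probes <- tibble(probe_id = pids,
                   mirna = sprintf("miR-%03d", seq_len(m)),
                   violation = violation)
  list(mirna = mirna_matrix(values, detection_p, probes), truth = truth)
}
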