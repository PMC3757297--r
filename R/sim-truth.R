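#' Realize the planted truth for a synthetic study
#'
#' Builds the per-sample latent drug-sensitivity score through which every
#' planted `*_auc` effect acts: the shared latent is a unit-variance mix of a
#' standard-normal base and the standardized dosages of `snp_auc` SNPs (weights
#' equal to the planted correlations), and each drug-specific sensitivity mixes
#' the shared latent with drug noise at correlation `drug_cor`. High
#' sensitivity maps to low AUC downstream. MicroRNA latent signals needed by
#' `mirna_probe` effects are realized here as well so expression and microRNA
#' generation stay mutually consistent.
#'
#' @param config a [sim_config()].
#' @param genotypes optional [genotype_matrix()]; required when `snp_auc`
#'   effects are planted (without it those contributions are skipped with a
#'   warning).
#' @return An object of class `planted_truth`: list with `latent` (tibble of
#'   per-sample shared and per-drug sensitivities), `mirna_latent` (matrix),
#'   and `effects` (the planted-effect tibble).
#' @export
simulate_truth <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "latent"))
  n <- sum(config$n_per_population)
  ids <- sample_ids(config)
  z_base <- rnorm(n)
  eps <- matrix(rnorm(n * length(config$drug_names)), nrow = n,
                dimnames = list(ids, config$drug_names))

  eff <- config$planted_effects
  snp_eff <- eff[eff$kind == "snp_auc", ]
  if (nrow(snp_eff) && is.null(genotypes)) {
    warn("snp_auc effects planted but no genotypes supplied; latent omits them")
    snp_eff <- snp_eff[0, ]
  }
  if (nrow(snp_eff)) {
    zg <- vapply(snp_eff$source, function(id) {
      g <- genotypes$dosage[ids, id]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      as.numeric(scale(g))
    }, numeric(n))
    w <- snp_eff$effect_size
    resid_var <- 1 - sum(w^2)
    if (resid_var < 0) abort("snp_auc effect sizes imply negative residual variance")
    s <- sqrt(resid_var) * z_base + as.numeric(zg %*% w)
  } else {
    s <- z_base
  }

  rho <- config$drug_cor
  s_drug <- rho * s + sqrt(1 - rho^2) * eps

  mirna_src <- unique(eff$source[eff$kind %in% c("mirna_auc", "mirna_probe")])
  mirna_latent <- NULL
  if (length(mirna_src)) {
    mirna_src <- sort(mirna_src)
    mirna_latent <- matrix(0, nrow = n, ncol = length(mirna_src),
                           dimnames = list(ids, mirna_src))
    for (mid in mirna_src) {
      a_row <- eff[eff$kind == "mirna_auc" & eff$source == mid, ]
      a <- if (nrow(a_row)) a_row$effect_size[1] else 0
      xi <- rnorm(n)
      mirna_latent[, mid] <- a * as.numeric(scale(s)) + sqrt(1 - a^2) * xi
    }
  }

  latent <- tibble(sample_id = ids, shared = s)
  for (d in config$drug_names) latent[[d]] <- s_drug[, d]

  structure(list(latent = latent, mirna_latent = mirna_latent, effects = eff),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth> ", nrow(x$latent), " samples; ", nrow(x$effects),
      " planted effects\n", sep = "")
  invisible(x)
}

# Solve mixing weights so a constructed feature hits target correlations with
# the (standardized) latent sensitivity and at most one extra driver.
# Returns the standardized feature vector.
plant_feature <- function(z_noise, s_std, r_s, driver_std = NULL, r_d = 0) {
  if (is.null(driver_std)) {
    if (abs(r_s) >= 1) abort("planted correlation must be inside (-1, 1)")
    return(r_s * s_std + sqrt(1 - r_s^2) * z_noise)
  }
  a <- cor(s_std, driver_std)
  c_s <- (r_s - a * r_d) / (1 - a^2)
  c_d <- (r_d - a * r_s) / (1 - a^2)
  expl <- c_s^2 + c_d^2 + 2 * c_s * c_d * a
  if (expl > 1) {
    abort("planted correlations are jointly infeasible for this feature")
  }
  c_s * s_std + c_d * driver_std + sqrt(1 - expl) * z_noise
}
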