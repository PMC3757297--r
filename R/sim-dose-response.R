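#' Simulate dose-response viability readouts
#'
#' Each sample's true curve is a four-parameter logistic in log10 dose with
#' top fixed at 1 (fraction-of-control scale), whose log10 IC50 and lower
#' asymptote are decreasing functions of the sample's drug-specific latent
#' sensitivity: sensitive lines shift left and die further down. Observed
#' viabilities add Normal(0, `noise_sd`) measurement noise per replicate,
#' truncated below at 0.
#'
#' True parameters: `log10_ic50 = 1.5 + shift_drug - 1.2 * s`,
#' `bottom = clamp(0.5 - 0.2 * s, 0.02, 0.95)`, `hill = 1.2`, where `s` is the
#' drug-specific sensitivity from the `planted_truth`.
#'
#' @param truth a `planted_truth` from [simulate_truth()].
#' @param config a [sim_config()].
#' @return tibble in long format (`sample_id`, `drug`, `dose_nM`, `replicate`,
#'   `viability`) with the per-sample true curve parameters attached as the
#'   `"true_params"` attribute.
#' @export
simulate_dose_response <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  if (any(config$dose_grid <= 0)) abort("doses must be positive")
  set.seed(sim_seed(config, "dose_response"))
  ids <- truth$latent$sample_id
  n <- length(ids)
  doses <- config$dose_grid
  reps <- config$replicates

  params <- purrr::map_dfr(config$drug_names, function(d) {
    s <- truth$latent[[d]]
    tibble(sample_id = ids, drug = d,
           bottom = pmin(pmax(0.5 - 0.2 * s, 0.02), 0.95),
           top = 1,
           log10_ic50 = 1.5 + config$drug_ic50_shift[[d]] - 1.2 * s,
           hill = 1.2)
  })

  obs <- params |>
    tidyr::expand_grid(dose_nM = doses, replicate = seq_len(reps)) |>
    mutate(viability = logistic_viability(dose_nM, bottom, top, log10_ic50, hill))
  obs$viability <- pmax(0, obs$viability + rnorm(nrow(obs), 0, config$noise_sd))
  out <- obs |> select(sample_id, drug, dose_nM, replicate, viability)
  attr(out, "true_params") <- params
  out
}

#' Run the whole synthetic study
#'
#' Convenience orchestrator: genotypes, covariates, shared planted truth,
#' expression, microRNA and dose-response data from one configuration, all
#' bit-reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes`, `covariates`, `expression`,
#'   `mirna`, `dose_response`, `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  truth <- simulate_truth(config, genotypes)
  expr <- simulate_expression(genotypes, config, covariates, truth)
  mir <- simulate_mirna(config, covariates, truth)
  dr <- simulate_dose_response(truth, config)
  list(genotypes = genotypes, covariates = covariates,
       expression = expr$expression, mirna = mir$mirna,
       dose_response = dr, truth = truth, config = config)
}
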