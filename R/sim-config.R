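#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic lymphoblastoid cell-line (LCL) pharmacogenomic study:
#' three ancestry groups genotyped genome-wide, log2-scale mRNA expression with
#' sex/race/batch structure, bead-array microRNA intensities with per-entry
#' detection p-values, and 8-point dose-response viability readouts for two
#' drugs acting through one shared latent drug-sensitivity score per sample.
#'
#' All randomness descends from `seed` through a fixed stream-splitting scheme
#' (one offset per generated matrix), so each matrix is reproducible in
#' isolation and the whole study is bit-identical across runs.
#'
#' @param n_per_population named integer vector of samples per ancestry group.
#' @param n_snps,n_probes,n_mirna feature counts for the three platforms.
#' @param n_mirna_extra_samples microRNA-assayed samples outside the
#'   dose-response cohort (platforms assay partially overlapping panels).
#' @param n_fail_mirna_probes,n_fail_mirna_samples,n_fail_mirna_sd sizes of the
#'   deliberate microRNA filter-cascade tranches: probes with >=80 percent
#'   undetected entries, samples with >=50 percent undetected entries (the
#'   extra samples are always in this tranche), and low-variability probes
#'   (SD below 0.40). Defaults reproduce a 733 -> 453 -> 228 probe cascade
#'   with 262 cohort samples retained.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)` controlling
#'   allele-frequency drift between populations.
#' @param maf_range interval in `(0, 0.5]` from which ancestral minor-allele
#'   frequencies are drawn uniformly.
#' @param missing_rate per-entry genotype missingness for well-behaved SNPs.
#' @param n_fail_call_rate,n_fail_maf,n_fail_hwe sizes of the deliberate
#'   QC-violation tranches (each SNP violates exactly one filter); these occupy
#'   the last columns of the genotype matrix so planted-effect SNPs (leading
#'   columns) are never sacrificed to QC.
#' @param n_low_expr number of probes generated with linear-scale mean below 50
#'   to exercise the low-expression candidate filter.
#' @param planted_effects tibble of planted effects, see [planted_effect()].
#' @param snp_annotation,probe_annotation optional tibbles pinning gene (and for
#'   SNPs, functional-class) annotation of specific features; remaining features
#'   are annotated at random.
#' @param dose_grid strictly increasing positive dose grid in nM.
#' @param replicates viability replicates per dose.
#' @param noise_sd measurement noise SD on the viability-fraction scale.
#' @param drug_names names of the two assayed drugs.
#' @param drug_cor correlation between each drug-specific sensitivity and the
#'   shared latent sensitivity (drives the inter-drug AUC correlation).
#' @param drug_ic50_shift named per-drug offsets of the log10 IC50 anchor.
#' @param batch_levels number of processing batches.
#' @param batch_sd,sex_sd,race_sd SDs (log2 units) of per-probe additive batch,
#'   sex and race effects on expression.
#' @param seed master seed (integer).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_population = c(CA = 87, AA = 91, HCA = 94),
                       n_snps = 5000,
                       n_probes = 2000,
                       n_mirna = 733,
                       n_mirna_extra_samples = 10,
                       n_fail_mirna_probes = 280,
                       n_fail_mirna_samples = 20,
                       n_fail_mirna_sd = 225,
                       fst = 0.02,
                       maf_range = c(0.1, 0.5),
                       missing_rate = 0.01,
                       n_fail_call_rate = 20,
                       n_fail_maf = 20,
                       n_fail_hwe = 20,
                       n_low_expr = 100,
                       planted_effects = default_planted_effects(),
                       snp_annotation = default_snp_annotation(),
                       probe_annotation = default_probe_annotation(),
                       dose_grid = 10^seq(-7, 3, length.out = 8),
                       replicates = 2,
                       noise_sd = 0.05,
                       drug_names = c("Rapamycin", "Everolimus"),
                       drug_cor = 0.92,
                       drug_ic50_shift = c(0, 0.2),
                       batch_levels = 4,
                       batch_sd = 0.3,
                       sex_sd = 0.1,
                       race_sd = 0.2,
                       seed = 1L) {
  counts <- c(n_per_population, n_snps = n_snps, n_probes = n_probes,
              n_mirna = n_mirna, replicates = replicates,
              batch_levels = batch_levels)
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("all counts must be positive integers")
  }
  if (is.null(names(n_per_population))) {
    names(n_per_population) <- paste0("POP", seq_along(n_per_population))
  }
  if (n_fail_mirna_samples < n_mirna_extra_samples) {
    abort("`n_fail_mirna_samples` must cover the extra (non-cohort) samples")
  }
  if (n_fail_mirna_samples - n_mirna_extra_samples >= sum(n_per_population)) {
    abort("`n_fail_mirna_samples` would empty the cohort")
  }
  if (n_fail_mirna_probes + n_fail_mirna_sd >= n_mirna) {
    abort("microRNA failure tranches exceed `n_mirna`")
  }
  if (!is.numeric(fst) || fst < 0 || fst >= 1) abort("`fst` must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must lie in [0, 1)")
  if (any(dose_grid <= 0) || is.unsorted(dose_grid, strictly = TRUE)) {
    abort("`dose_grid` must be strictly increasing and positive")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (length(drug_names) < 1) abort("at least one drug required")
  if (drug_cor <= 0 || drug_cor > 1) abort("`drug_cor` must lie in (0, 1]")
  if (length(drug_ic50_shift) != length(drug_names)) {
    drug_ic50_shift <- rep_len(drug_ic50_shift, length(drug_names))
  }
  names(drug_ic50_shift) <- drug_names
  planted_effects <- validate_planted_effects(planted_effects, n_snps, n_probes, n_mirna)
  cfg <- list(
    n_per_population = n_per_population, n_snps = n_snps, n_probes = n_probes,
    n_mirna = n_mirna, n_mirna_extra_samples = n_mirna_extra_samples,
    n_fail_mirna_probes = n_fail_mirna_probes,
    n_fail_mirna_samples = n_fail_mirna_samples,
    n_fail_mirna_sd = n_fail_mirna_sd, fst = fst,
    maf_range = maf_range, missing_rate = missing_rate,
    n_fail_call_rate = n_fail_call_rate, n_fail_maf = n_fail_maf,
    n_fail_hwe = n_fail_hwe, n_low_expr = n_low_expr,
    planted_effects = planted_effects, snp_annotation = snp_annotation,
    probe_annotation = probe_annotation, dose_grid = dose_grid,
    replicates = replicates, noise_sd = noise_sd, drug_names = drug_names,
    drug_cor = drug_cor, drug_ic50_shift = drug_ic50_shift,
    batch_levels = batch_levels, batch_sd = batch_sd, sex_sd = sex_sd,
    race_sd = race_sd, seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", sum(x$n_per_population), " samples (",
      paste(names(x$n_per_population), x$n_per_population, sep = "=", collapse = ", "),
      "); ", x$n_snps, " SNPs, ", x$n_probes, " probes, ", x$n_mirna,
      " miRNAs; fst=", x$fst, "; seed=", x$seed, "\n", sep = "")
  cat("  planted effects: ", nrow(x$planted_effects), "\n", sep = "")
  invisible(x)
}

#' Declare one planted effect
#'
#' `effect_size` is on the correlation scale and, for `*_auc` kinds, is the
#' target correlation of the feature with the latent drug *sensitivity* (high
#' sensitivity means low AUC, so the realized feature-AUC correlation carries
#' the opposite sign, attenuated by `drug_cor`).
#'
#' @param kind one of `"snp_auc"`, `"probe_auc"`, `"snp_probe"`, `"mirna_auc"`,
#'   `"mirna_probe"`.
#' @param source feature id the effect emanates from.
#' @param target `"auc"` or the receiving probe id.
#' @param effect_size nonzero correlation in (-1, 1).
#' @return one-row tibble.
#' @export
planted_effect <- function(kind, source, target, effect_size) {
  kinds <- c("snp_auc", "probe_auc", "snp_probe", "mirna_auc", "mirna_probe")
  if (!kind %in% kinds) abort(paste0("unknown effect kind: ", kind))
  if (effect_size == 0 || abs(effect_size) >= 1) {
    abort("`effect_size` must be nonzero and inside (-1, 1)")
  }
  tibble(kind = kind, source = source, target = target,
         effect_size = as.numeric(effect_size))
}

validate_planted_effects <- function(effects, n_snps, n_probes, n_mirna) {
  if (is.null(effects) || nrow(effects) == 0) {
    return(tibble(kind = character(), source = character(),
                  target = character(), effect_size = numeric()))
  }
  effects <- as_tibble(effects)
  stopifnot(all(c("kind", "source", "target", "effect_size") %in% names(effects)))
  if (any(effects$effect_size == 0) || any(abs(effects$effect_size) >= 1)) {
    abort("planted effect sizes must be nonzero and inside (-1, 1)")
  }
  ids <- list(snp = snp_ids(n_snps), probe = probe_ids(n_probes),
              mirna = mirna_ids(n_mirna))
  src_kind <- sub("_.*$", "", effects$kind)
  ok_src <- vapply(seq_len(nrow(effects)), function(i) {
    effects$source[i] %in% ids[[src_kind[i]]]
  }, logical(1))
  tgt_kind <- sub("^.*_", "", effects$kind)
  ok_tgt <- vapply(seq_len(nrow(effects)), function(i) {
    if (tgt_kind[i] == "auc") effects$target[i] == "auc"
    else effects$target[i] %in% ids$probe
  }, logical(1))
  if (!all(ok_src) || !all(ok_tgt)) {
    bad <- effects[!(ok_src & ok_tgt), ]
    abort(paste0("planted effect references unknown feature id(s): ",
                 paste(unique(c(bad$source, bad$target)), collapse = ", ")))
  }
  effects
}

snp_ids <- function(n) sprintf("snp_%05d", seq_len(n))
probe_ids <- function(n) sprintf("probe_%04d", seq_len(n))
mirna_ids <- function(n) sprintf("mir_%03d", seq_len(n))

#' Default planted effect panel
#'
#' Plants the candidate-selection structure every downstream rule needs at
#' least one positive example of: four single-probe expression genes, one
#' two-probe gene, one two-SNP gene, one nonsynonymous SNP gene, one
#' SNP-probe-phenotype triangle, and one microRNA associated with sensitivity
#' that also represses three of the sensitivity-associated probes.
#'
#' @return tibble of planted effects.
#' @export
default_planted_effects <- function() {
  bind_rows(
    planted_effect("probe_auc", "probe_0001", "auc", 0.45),   # gene EXPA
    planted_effect("probe_auc", "probe_0002", "auc", -0.45),  # gene EXPB
    planted_effect("probe_auc", "probe_0003", "auc", 0.45),   # gene EXPC
    planted_effect("probe_auc", "probe_0004", "auc", 0.45),   # gene EXPD
    planted_effect("probe_auc", "probe_0005", "auc", 0.40),   # gene EXP2P
    planted_effect("probe_auc", "probe_0006", "auc", 0.40),   # gene EXP2P
    planted_effect("snp_auc", "snp_00001", "auc", 0.45),      # gene SNPM
    planted_effect("snp_auc", "snp_00002", "auc", 0.45),      # gene SNPM
    planted_effect("snp_auc", "snp_00003", "auc", 0.45),      # gene SNPNS (nonsyn)
    planted_effect("snp_auc", "snp_00004", "auc", 0.45),      # hosted by TRIHOST
    planted_effect("snp_probe", "snp_00004", "probe_0007", 0.50),
    planted_effect("probe_auc", "probe_0007", "auc", 0.35),   # gene TRITGT
    planted_effect("mirna_auc", "mir_001", "auc", 0.45),
    planted_effect("mirna_probe", "mir_001", "probe_0001", -0.40),
    planted_effect("mirna_probe", "mir_001", "probe_0002", -0.40),
    planted_effect("mirna_probe", "mir_001", "probe_0003", -0.40)
  )
}

#' @rdname default_planted_effects
#' @export
default_snp_annotation <- function() {
  tibble(
    snp_id = c("snp_00001", "snp_00002", "snp_00003", "snp_00004"),
    gene = c("SNPM", "SNPM", "SNPNS", "TRIHOST"),
    func_class = c("intron", "intron", "nonsynonymous", "upstream")
  )
}

#' @rdname default_planted_effects
#' @export
default_probe_annotation <- function() {
  tibble(
    probe_id = sprintf("probe_%04d", 1:9),
    gene = c("EXPA", "EXPB", "EXPC", "EXPD", "EXP2P", "EXP2P", "TRITGT",
             "SNPM", "SNPNS")
  )
}

# fixed stream offsets: each generated matrix draws from seed + offset so it is
# reproducible in isolation
sim_seed <- function(config, stream) {
  offsets <- c(latent = 1L, genotypes = 2L, covariates = 3L, expression = 4L,
               mirna = 5L, dose_response = 6L)
  config$seed + offsets[[stream]]
}

sample_ids <- function(config) {
  sprintf("LCL%03d", seq_len(sum(config$n_per_population)))
}

population_labels <- function(config) {
  rep(names(config$n_per_population), config$n_per_population)
}
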