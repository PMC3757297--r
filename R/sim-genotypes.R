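#' Simulate a multi-population genotype matrix
#'
#' Draws ancestral minor-allele frequencies uniformly from `maf_range`,
#' diverges them per population with the Balding-Nichols Beta model
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`; `fst = 0` disables
#' divergence), and samples genotypes in Hardy-Weinberg equilibrium within
#' each population. Missing entries are injected at `missing_rate`.
#'
#' Three deliberate QC-violation tranches occupy the trailing columns so their
#' downstream filter attribution is known by construction: SNPs with entry
#' missingness 0.20 (call-rate failures), SNPs with all population frequencies
#' pinned at 0.02 (MAF failures), and all-heterozygote SNPs (HWE failures).
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] whose `snps` metadata carries `chr`, `pos`,
#'   `ref`, `alt`, `gene`, `func_class` and the generator's `violation` label
#'   (`"none"`, `"call_rate"`, `"maf"`, `"hwe"`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "genotypes"))
  n <- sum(config$n_per_population)
  m <- config$n_snps
  pops <- population_labels(config)
  n_fail <- config$n_fail_call_rate + config$n_fail_maf + config$n_fail_hwe
  if (n_fail >= m) abort("QC-violation tranches exceed `n_snps`")

  violation <- rep("none", m)
  if (config$n_fail_hwe > 0) violation[(m - config$n_fail_hwe + 1):m] <- "hwe"
  if (config$n_fail_maf > 0) {
    violation[(m - config$n_fail_hwe - config$n_fail_maf + 1):(m - config$n_fail_hwe)] <- "maf"
  }
  if (config$n_fail_call_rate > 0) {
    violation[(m - n_fail + 1):(m - n_fail + config$n_fail_call_rate)] <- "call_rate"
  }

  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
  p_anc[violation == "maf"] <- 0.02

  pop_names <- names(config$n_per_population)
  # population allele frequencies: Balding-Nichols Beta draw around ancestry
  pf <- matrix(0, nrow = length(pop_names), ncol = m,
               dimnames = list(pop_names, NULL))
  for (k in seq_along(pop_names)) {
    if (config$fst == 0) {
      pf[k, ] <- p_anc
    } else {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      pf[k, ] <- rbeta(m, a, b)
    }
  }
  pf[, violation == "maf"] <- 0.02

  dosage <- matrix(0L, nrow = n, ncol = m)
  for (k in seq_along(pop_names)) {
    rows <- which(pops == pop_names[k])
    dosage[rows, ] <- rbinom(length(rows) * m, 2L,
                             rep(pf[k, ], each = length(rows)))
  }
  dosage[, violation == "hwe"] <- 1L

  storage.mode(dosage) <- "double"
  miss_rate <- ifelse(violation == "call_rate", 0.20,
                      ifelse(violation == "hwe", 0, config$missing_rate))
  if (any(miss_rate > 0)) {
    u <- matrix(runif(n * m), nrow = n)
    dosage[u < rep(miss_rate, each = n)] <- NA_real_
  }
  rownames(dosage) <- sample_ids(config)
  colnames(dosage) <- snp_ids(m)

  snps <- annotate_snps(config, violation)
  genotype_matrix(dosage, snps)
}

annotate_snps <- function(config, violation) {
  m <- config$n_snps
  ids <- snp_ids(m)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1), character(1))
  chr <- sort(sample(1:22, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chr), function(i) {
    sort(sample.int(2.4e8, length(i)))
  }), use.names = FALSE)
  # ~3 null SNPs per gene; planted SNPs take their pinned annotation below
  gene <- sprintf("SGEN%04d", ceiling(seq_len(m) / 3))
  func_class <- sample(c("intron", "intergenic", "upstream", "downstream",
                         "utr", "nonsynonymous"), m, replace = TRUE,
                       prob = c(0.35, 0.30, 0.10, 0.10, 0.14, 0.01))
  snps <- tibble(snp_id = ids, chr = chr, pos = pos, ref = ref, alt = alt,
                 gene = gene, func_class = func_class, violation = violation)
  pin <- config$snp_annotation
  if (!is.null(pin) && nrow(pin)) {
    i <- match(pin$snp_id, snps$snp_id)
    ok <- !is.na(i)
    snps$gene[i[ok]] <- pin$gene[ok]
    if ("func_class" %in% names(pin)) snps$func_class[i[ok]] <- pin$func_class[ok]
  }
  snps
}

#' Simulate per-sample covariates
#'
#' Sex is drawn uniformly, race is the ancestry group, and batch assigns each
#' sample to one of `batch_levels` processing batches.
#'
#' @param config a [sim_config()].
#' @return tibble with `sample_id`, `sex`, `race`, `batch`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "covariates"))
  n <- sum(config$n_per_population)
  tibble(
    sample_id = sample_ids(config),
    sex = sample(c("F", "M"), n, replace = TRUE),
    race = population_labels(config),
    batch = sample(sprintf("B%d", seq_len(config$batch_levels)), n, replace = TRUE)
  )
}
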