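#' Pipeline run configuration
#'
#' Collects the input paths and every analysis threshold, pre-populated with
#' the pipeline defaults: SNP QC at call rate 0.95 / MAF 0.05 / HWE p 0.001,
#' K = 4 stratification components, AUC integration over 1e-7 to 1e3 nM,
#' triangulation cutoffs 1e-4 / 1e-4 / 1e-3, candidate cutoffs 1e-4 and 1e-5,
#' linear-expression floor 50, microRNA cascade 0.01 / 0.80 / 0.50 / 0.40 and
#' Bonferroni alpha 0.05. The configuration round-trips through JSON.
#'
#' @param input_dir directory holding the study files as written by
#'   [write_study()] (individual paths may be overridden).
#' @param out_dir optional output directory; when set, every result table and
#'   a run manifest are written there.
#' @param genotypes,expression,mirna,covariates,dose_response input paths.
#' @param call_rate_min,maf_min,hwe_p_min SNP QC cutoffs.
#' @param k_pcs number of stratification principal components.
#' @param snp_adjustment `"symmetric"` residualizes SNP dosages on the PCs as
#'   well as the phenotype; `"phenotype_only"` adjusts only the phenotype.
#' @param auc_lo_nM,auc_hi_nM AUC integration range.
#' @param triangle_thresholds length-3 p cutoffs for [triangulate()].
#' @param p_strong,p_extreme candidate-selection cutoffs.
#' @param expr_threshold linear-scale low-expression floor.
#' @param det_alpha,probe_missing_max,sample_missing_max,sd_min microRNA
#'   cascade parameters.
#' @param mirna_alpha Bonferroni alpha for the microRNA screen.
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic; only synthetic generation consumes randomness).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = NULL,
                       genotypes = file.path(input_dir, "genotypes.tsv"),
                       expression = file.path(input_dir, "expression.tsv"),
                       mirna = file.path(input_dir, "mirna.tsv"),
                       covariates = file.path(input_dir, "covariates.tsv"),
                       dose_response = file.path(input_dir, "dose_response.tsv"),
                       call_rate_min = 0.95, maf_min = 0.05, hwe_p_min = 0.001,
                       k_pcs = 4, snp_adjustment = c("symmetric", "phenotype_only"),
                       auc_lo_nM = 1e-7, auc_hi_nM = 1e3,
                       triangle_thresholds = c(1e-4, 1e-4, 1e-3),
                       p_strong = 1e-4, p_extreme = 1e-5, expr_threshold = 50,
                       det_alpha = 0.01, probe_missing_max = 0.80,
                       sample_missing_max = 0.50, sd_min = 0.40,
                       mirna_alpha = 0.05, seed = 1L) {
  snp_adjustment <- match.arg(snp_adjustment)
  thresholds <- c(call_rate_min = call_rate_min, maf_min = maf_min,
                  hwe_p_min = hwe_p_min, p_strong = p_strong,
                  p_extreme = p_extreme, det_alpha = det_alpha,
                  probe_missing_max = probe_missing_max,
                  sample_missing_max = sample_missing_max, sd_min = sd_min,
                  mirna_alpha = mirna_alpha, triangle_thresholds)
  if (any(thresholds <= 0) || any(thresholds > 1)) {
    abort("all probability thresholds must lie in (0, 1]")
  }
  if (length(triangle_thresholds) != 3 || any(triangle_thresholds >= 1)) {
    abort("`triangle_thresholds` must be three p cutoffs in (0, 1)")
  }
  if (auc_lo_nM <= 0 || auc_hi_nM <= auc_lo_nM) abort("need 0 < auc_lo_nM < auc_hi_nM")
  if (k_pcs <= 0) abort("`k_pcs` must be positive")
  structure(list(
    genotypes = genotypes, expression = expression, mirna = mirna,
    covariates = covariates, dose_response = dose_response, out_dir = out_dir,
    call_rate_min = call_rate_min, maf_min = maf_min, hwe_p_min = hwe_p_min,
    k_pcs = k_pcs, snp_adjustment = snp_adjustment,
    auc_lo_nM = auc_lo_nM, auc_hi_nM = auc_hi_nM,
    triangle_thresholds = triangle_thresholds, p_strong = p_strong,
    p_extreme = p_extreme, expr_threshold = expr_threshold,
    det_alpha = det_alpha, probe_missing_max = probe_missing_max,
    sample_missing_max = sample_missing_max, sd_min = sd_min,
    mirna_alpha = mirna_alpha, seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> inputs:\n")
  for (f in c("genotypes", "expression", "mirna", "covariates", "dose_response")) {
    cat("  ", f, ": ", x[[f]], "\n", sep = "")
  }
  cat("  out_dir: ", x$out_dir %||% "<none>", "\n", sep = "")
  invisible(x)
}

# residualize feature columns on a covariate design, preserving NA patterns
adjust_feature_matrix <- function(X, design) {
  design <- as.data.frame(design)
  design[] <- lapply(design, function(col) if (is.character(col)) factor(col) else col)
  M <- stats::model.matrix(~ ., data = design)
  out <- X
  complete <- !is.na(X)
  all_complete <- colSums(!complete) == 0
  if (any(all_complete)) {
    out[, all_complete] <- lm.fit(M, X[, all_complete, drop = FALSE])$residuals
  }
  for (j in which(!all_complete)) {
    ok <- complete[, j]
    if (sum(ok) <= ncol(M)) next
    out[ok, j] <- lm.fit(M[ok, , drop = FALSE], X[ok, j])$residuals
  }
  out
}

#' Run the full pipeline
#'
#' Executes dose-response fitting, QC/preprocessing, per-drug association
#' scans of SNPs, expression probes and microRNA probes, triangulation with
#' cross-drug overlap, candidate selection and the microRNA screen. With
#' `config$out_dir` set, all result tables are written as tab-separated files
#' together with a JSON run manifest (input hashes, config echo, package
#' version, per-stage timings and row counts). Given identical inputs and
#' configuration the result tables are byte-identical across reruns.
#'
#' @param config a [run_config()].
#' @param manual optional manual candidate additions, see [select_candidates()].
#' @return list with `auc`, `qc_report`, `pcs`, `phenotypes`, `snp_assoc`,
#'   `expr_assoc`, `mirna_assoc`, `triangles`, `triangle_overlap`,
#'   `candidates`, `candidate_summary`, `mirna_screen`, `manifest`.
#' @export
run_pipeline <- function(config, manual = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_all <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  for (f in c("genotypes", "expression", "mirna", "covariates", "dose_response")) {
    if (!file.exists(config[[f]])) abort(paste0("input not readable: ", config[[f]]))
  }
  gm <- tick("read_genotypes", read_genotypes(config$genotypes))
  em <- tick("read_expression", read_expression(config$expression))
  mm <- tick("read_mirna", read_mirna(config$mirna))
  covariates <- read_covariates(config$covariates)
  dr <- read_dose_response(config$dose_response)
  drugs <- sort(unique(dr$drug))
  if (length(drugs) != 2) abort("the pipeline expects exactly two drugs")

  inform("stage dose_response: fitting logistic family and integrating AUC")
  auc <- tick("dose_response",
              derive_auc_phenotypes(dr, config$auc_lo_nM, config$auc_hi_nM))

  inform(paste0("stage snp_qc: ", ncol(gm$dosage), " SNPs in"))
  qc <- tick("snp_qc", snp_qc(gm, config$call_rate_min, config$maf_min,
                              config$hwe_p_min))
  inform(paste0("stage snp_qc: ", ncol(qc$genotypes$dosage), " SNPs retained"))
  pcs <- tick("pca", compute_pcs(qc$genotypes, config$k_pcs))

  expr_adj <- tick("preprocess_expression", preprocess_expression(em, covariates))
  cascade <- tick("mirna_cascade",
                  mirna_filter_cascade(mm, config$det_alpha,
                                       config$probe_missing_max,
                                       config$sample_missing_max, config$sd_min))
  mir_f <- cascade$mirna
  in_cohort <- rownames(mir_f$values) %in% covariates$sample_id
  if (any(!in_cohort)) {
    inform(paste0("dropping ", sum(!in_cohort),
                  " microRNA sample(s) without covariates"))
    mir_f <- mirna_matrix(mir_f$values[in_cohort, , drop = FALSE],
                          mir_f$detection_p[in_cohort, , drop = FALSE],
                          mir_f$probes)
  }
  mir_adj <- tick("preprocess_mirna", preprocess_mirna(mir_f, covariates))

  snp_features <- qc$genotypes$dosage
  if (config$snp_adjustment == "symmetric") {
    design <- pcs$scores[match(rownames(snp_features), pcs$scores$sample_id),
                         setdiff(names(pcs$scores), "sample_id")]
    snp_features <- tick("adjust_snps", adjust_feature_matrix(snp_features, design))
  }

  phenotypes <- list()
  snp_assoc <- list()
  expr_assoc <- list()
  mirna_assoc <- list()
  triangles <- list()
  for (d in drugs) {
    pheno <- preprocess_phenotype(auc |> filter(drug == d), covariates, pcs)
    phenotypes[[d]] <- pheno
    inform(paste0("stage association (", d, "): ", ncol(snp_features), " SNPs, ",
                  ncol(expr_adj$values), " probes, ", ncol(mir_adj$values),
                  " microRNAs"))
    snp_assoc[[d]] <- pearson_scan(snp_features, pheno, kind = "snp")
    expr_assoc[[d]] <- pearson_scan(expr_adj, pheno, kind = "probe")
    mirna_assoc[[d]] <- pearson_scan(mir_adj, pheno, kind = "mirna")
    triangles[[d]] <- triangulate(snp_assoc[[d]], expr_assoc[[d]],
                                  genotype_matrix_from(snp_features, qc$genotypes$snps),
                                  expr_adj, config$triangle_thresholds, drug = d)
  }
  tri_overlap <- overlap_across_drugs(triangles[[drugs[1]]], triangles[[drugs[2]]])
  candidates <- tick("select_candidates",
                     select_candidates(expr_assoc, snp_assoc, tri_overlap, em,
                                       qc$genotypes$snps, config$p_strong,
                                       config$p_extreme, config$expr_threshold,
                                       manual = manual))
  screen <- tick("mirna_screen",
                 mirna_screen(mirna_assoc, expr_assoc, expr_adj, mir_adj,
                              config$mirna_alpha, config$p_strong))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pgxscan")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(config[c(
      "genotypes", "expression", "mirna", "covariates", "dose_response")]))),
    n_samples = nrow(covariates),
    n_snps_in = ncol(gm$dosage), n_snps_retained = ncol(qc$genotypes$dosage),
    n_probes = ncol(em$values),
    n_mirna_in = ncol(mm$values), n_mirna_retained = ncol(mir_adj$values),
    n_candidates = length(unique(candidates$gene)),
    timings_s = t_all
  )

  res <- list(auc = auc, qc_report = qc$report, pcs = pcs,
              phenotypes = phenotypes, snp_assoc = snp_assoc,
              expr_assoc = expr_assoc, mirna_assoc = mirna_assoc,
              triangles = triangles, triangle_overlap = tri_overlap,
              candidates = candidates,
              candidate_summary = summarise_candidates(candidates),
              mirna_screen = screen, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, drugs, config)
  invisible(res)
}

genotype_matrix_from <- function(values, snps) {
  # adjusted dosages are continuous; bypass the 0/1/2 check but keep metadata
  structure(list(dosage = values, snps = snps[match(colnames(values), snps$snp_id), ]),
            class = "genotype_matrix")
}

write_pipeline_outputs <- function(res, drugs, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  pgx_write_tsv(res$auc, out("auc.tsv"))
  qc_tbl <- res$qc_report |>
    bind_rows(tibble(filter = "retained",
                     n_removed = attr(res$qc_report, "n_retained")))
  pgx_write_tsv(attr(res$qc_report, "details"), out("snp_qc_details.tsv"))
  pgx_write_tsv(qc_tbl, out("snp_qc_report.tsv"))
  pgx_write_tsv(res$pcs$scores, out("pcs.tsv"))
  for (d in drugs) {
    pgx_write_tsv(res$phenotypes[[d]], out(paste0("phenotype_", tolower(d), ".tsv")))
    for (kind in c("snp", "expr", "mirna")) {
      tbl <- res[[paste0(kind, "_assoc")]][[d]]
      pgx_write_tsv(tbl, out(paste0("assoc_", kind, "_", tolower(d), ".tsv")))
    }
    pgx_write_tsv(res$triangles[[d]], out(paste0("triangles_", tolower(d), ".tsv")))
  }
  pgx_write_tsv(res$triangle_overlap, out("triangle_overlap.tsv"))
  pgx_write_tsv(res$candidates, out("candidates.tsv"))
  pgx_write_tsv(res$candidate_summary, out("candidate_summary.tsv"))
  pgx_write_tsv(res$mirna_screen$associations, out("mirna_screen.tsv"))
  pgx_write_tsv(res$mirna_screen$pairs, out("mirna_pairs.tsv"))
  jsonlite::write_json(res$manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
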