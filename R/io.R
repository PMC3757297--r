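# On-disk dialect: tab-separated, UTF-8, "." for missing, mandatory headers.
# Matrices are stored features x samples (first column the feature id), which
# diffs cleanly and matches how array vendors ship data.

pgx_read_tsv <- function(path, ...) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE, progress = FALSE, ...)
}

pgx_write_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = ".", progress = FALSE)
}

matrix_to_table <- function(mat, id_col) {
  out <- as_tibble(t(mat))
  dplyr::bind_cols(tibble("{id_col}" := colnames(mat)), out)
}

table_to_matrix <- function(tbl, id_col) {
  ids <- tbl[[id_col]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated feature id in ", id_col, ": ",
                 ids[duplicated(ids)][1]))
  }
  mat <- t(as.matrix(tbl[setdiff(names(tbl), id_col)]))
  colnames(mat) <- ids
  mat
}

#' Write / read a genotype matrix
#'
#' The matrix file stores SNPs x samples dosages (0/1/2, `.` for missing);
#' SNP metadata travels in a sidecar table keyed by `snp_id`.
#'
#' @param gm a [genotype_matrix()].
#' @param path matrix file path.
#' @param meta_path sidecar metadata path (default `<path>.meta.tsv`).
#' @return `write_genotypes()` returns the paths invisibly; `read_genotypes()`
#'   returns a [genotype_matrix()].
#' @export
write_genotypes <- function(gm, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pgx_write_tsv(matrix_to_table(gm$dosage, "snp_id"), path)
  pgx_write_tsv(gm$snps, meta_path)
  invisible(c(path, meta_path))
}

#' @rdname write_genotypes
#' @param format `"matrix"` (the package dialect) or `"vcf"` (dosage read as
#'   the alternate-allele count; records with any missing allele become
#'   missing; non-biallelic records are skipped with a message). VCF reading
#'   requires the vcfR package.
#' @export
read_genotypes <- function(path, meta_path = paste0(path, ".meta.tsv"),
                           format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  tbl <- pgx_read_tsv(path)
  if (names(tbl)[1] != "snp_id") abort("genotype matrix must start with `snp_id`")
  mat <- table_to_matrix(tbl, "snp_id")
  snps <- if (file.exists(meta_path)) pgx_read_tsv(meta_path) else NULL
  genotype_matrix(mat, snps)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  if (any(!biallelic)) {
    inform(paste0("skipping ", sum(!biallelic), " non-biallelic VCF record(s)"))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  rownames(dos) <- ids
  snps <- tibble(snp_id = ids, chr = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 ref = fix[, "REF"], alt = fix[, "ALT"])
  genotype_matrix(t(dos), snps)
}

#' Write / read an expression matrix
#'
#' Probes x samples log2 values with a sidecar probe annotation table.
#'
#' @param em an [expression_matrix()].
#' @param path matrix file path.
#' @param meta_path sidecar annotation path (default `<path>.meta.tsv`).
#' @export
write_expression <- function(em, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(em, "expression_matrix"))
  pgx_write_tsv(matrix_to_table(em$values, "probe_id"), path)
  pgx_write_tsv(em$probes, meta_path)
  invisible(c(path, meta_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(path, meta_path = paste0(path, ".meta.tsv")) {
  tbl <- pgx_read_tsv(path)
  if (names(tbl)[1] != "probe_id") abort("expression matrix must start with `probe_id`")
  mat <- table_to_matrix(tbl, "probe_id")
  probes <- if (file.exists(meta_path)) pgx_read_tsv(meta_path) else NULL
  expression_matrix(mat, probes)
}

#' Write / read a microRNA matrix with detection p-values
#'
#' Two probes x samples tables (intensities and detection p-values) plus a
#' probe metadata sidecar.
#'
#' @param mm a [mirna_matrix()].
#' @param path intensity matrix path.
#' @param detection_path detection p matrix path (default `<path>.detp.tsv`).
#' @param meta_path probe metadata path (default `<path>.meta.tsv`).
#' @export
write_mirna <- function(mm, path, detection_path = paste0(path, ".detp.tsv"),
                        meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(mm, "mirna_matrix"))
  pgx_write_tsv(matrix_to_table(mm$values, "probe_id"), path)
  pgx_write_tsv(matrix_to_table(mm$detection_p, "probe_id"), detection_path)
  pgx_write_tsv(mm$probes, meta_path)
  invisible(c(path, detection_path, meta_path))
}

#' @rdname write_mirna
#' @export
read_mirna <- function(path, detection_path = paste0(path, ".detp.tsv"),
                       meta_path = paste0(path, ".meta.tsv")) {
  vals <- table_to_matrix(pgx_read_tsv(path), "probe_id")
  detp <- table_to_matrix(pgx_read_tsv(detection_path), "probe_id")
  if (!identical(dimnames(vals), dimnames(detp))) {
    abort("intensity and detection matrices disagree on samples/probes")
  }
  probes <- if (file.exists(meta_path)) pgx_read_tsv(meta_path) else NULL
  mirna_matrix(vals, detp, probes)
}

#' Write / read the covariate table
#' @param covariates tibble `sample_id`, `sex`, `race`, `batch`.
#' @param path file path.
#' @export
write_covariates <- function(covariates, path) {
  pgx_write_tsv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  tbl <- pgx_read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "sex", "race", "batch")
  if (!all(need %in% names(tbl))) {
    abort("covariate table needs sample_id, sex, race, batch columns")
  }
  tbl
}

#' Write / read the long-format dose-response table
#' @param data tibble `sample_id`, `drug`, `dose_nM`, `replicate`, `viability`.
#' @param path file path.
#' @export
write_dose_response <- function(data, path) {
  pgx_write_tsv(data[c("sample_id", "drug", "dose_nM", "replicate", "viability")],
                path)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  tbl <- pgx_read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), drug = readr::col_character(),
    dose_nM = readr::col_double(), replicate = readr::col_integer(),
    viability = readr::col_double()))
  if (any(tbl$dose_nM <= 0)) abort("doses must be positive")
  tbl
}

#' Write / read the planted-truth record (JSON)
#' @param truth a `planted_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  obj <- list(effects = truth$effects, latent = truth$latent)
  if (!is.null(truth$mirna_latent)) {
    obj$mirna_latent <- dplyr::bind_cols(
      tibble(sample_id = rownames(truth$mirna_latent)),
      as_tibble(truth$mirna_latent))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ml <- NULL
  if (!is.null(obj$mirna_latent)) {
    ml <- as.matrix(obj$mirna_latent[setdiff(names(obj$mirna_latent), "sample_id")])
    rownames(ml) <- obj$mirna_latent$sample_id
  }
  effects <- as_tibble(obj$effects)
  if (nrow(effects) == 0) {
    effects <- tibble(kind = character(), source = character(),
                      target = character(), effect_size = numeric())
  }
  structure(list(latent = as_tibble(obj$latent), mirna_latent = ml,
                 effects = effects),
            class = "planted_truth")
}

#' Write a full synthetic study to a directory
#'
#' Emits every input the pipeline reads (genotypes + metadata, expression,
#' microRNA + detection p, covariates, dose-response) plus the truth record.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    mirna = file.path(dir, "mirna.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    dose_response = file.path(dir, "dose_response.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes(study$genotypes, paths["genotypes"])
  write_expression(study$expression, paths["expression"])
  write_mirna(study$mirna, paths["mirna"])
  write_covariates(study$covariates, paths["covariates"])
  write_dose_response(study$dose_response, paths["dose_response"])
  write_truth(study$truth, paths["truth"])
  invisible(paths)
}
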