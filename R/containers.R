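#' Sample-by-SNP genotype container
#'
#' Holds a numeric dosage matrix (samples in rows, SNPs in columns, entries in
#' \{0, 1, 2, NA\} counting alternate alleles) together with per-SNP metadata.
#'
#' @param dosage numeric matrix, samples x SNPs, with row and column names.
#' @param snps tibble of SNP metadata with at least `snp_id`; optionally
#'   `chr`, `pos`, `ref`, `alt`, `gene`, `func_class`. `func_class` uses a
#'   controlled vocabulary (`"nonsynonymous"`, `"intron"`, `"upstream"`,
#'   `"downstream"`, `"utr"`, `"intergenic"`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)), !is.null(colnames(dosage)))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  if (is.null(snps)) {
    snps <- tibble(snp_id = colnames(dosage))
  }
  snps <- as_tibble(snps)
  if (!"snp_id" %in% names(snps)) abort("`snps` metadata needs a `snp_id` column")
  if (anyDuplicated(snps$snp_id)) {
    dup <- snps$snp_id[duplicated(snps$snp_id)][1]
    abort(paste0("duplicated SNP id in metadata: ", dup))
  }
  if (!setequal(snps$snp_id, colnames(dosage))) {
    abort("`snps$snp_id` must match the dosage column names")
  }
  snps <- snps[match(colnames(dosage), snps$snp_id), ]
  if ("func_class" %in% names(snps)) {
    vocab <- c("nonsynonymous", "synonymous", "intron", "upstream",
               "downstream", "utr", "intergenic", NA)
    if (!all(snps$func_class %in% vocab)) {
      abort("unknown `func_class` value in SNP metadata")
    }
  }
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs; ", sum(is.na(x$dosage)), " missing entries\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample-by-probe expression container
#'
#' Values are on the log2 scale (post-normalization) with samples in rows and
#' probes in columns. Probe metadata maps probes to gene symbols.
#'
#' @param values numeric matrix, samples x probes, with dimnames.
#' @param probes tibble with `probe_id` and optionally `gene`, `chr`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probes = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (is.null(probes)) probes <- tibble(probe_id = colnames(values))
  probes <- as_tibble(probes)
  if (!"probe_id" %in% names(probes)) abort("`probes` metadata needs a `probe_id` column")
  if (!setequal(probes$probe_id, colnames(values))) {
    abort("`probes$probe_id` must match the value column names")
  }
  probes <- probes[match(colnames(values), probes$probe_id), ]
  structure(list(values = values, probes = probes), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " probes\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Sample-by-probe microRNA container
#'
#' Carries raw (pre-transform) intensities plus a per-entry detection p-value
#' matrix of identical shape, as produced by bead-array scanners.
#'
#' @param values numeric matrix, samples x probes, with dimnames.
#' @param detection_p numeric matrix in \[0, 1\], same shape as `values`.
#' @param probes tibble with `probe_id` and optionally `mirna` name.
#' @return An object of class `mirna_matrix`.
#' @export
mirna_matrix <- function(values, detection_p, probes = NULL) {
  stopifnot(is.matrix(values), is.matrix(detection_p),
            identical(dim(values), dim(detection_p)),
            !is.null(rownames(values)), !is.null(colnames(values)))
  dp <- detection_p[!is.na(detection_p)]
  if (length(dp) && (min(dp) < 0 || max(dp) > 1)) {
    abort("detection p-values must lie in [0, 1]")
  }
  if (is.null(probes)) probes <- tibble(probe_id = colnames(values))
  probes <- as_tibble(probes)
  if (!"probe_id" %in% names(probes)) abort("`probes` metadata needs a `probe_id` column")
  probes <- probes[match(colnames(values), probes$probe_id), ]
  structure(list(values = values, detection_p = detection_p, probes = probes),
            class = "mirna_matrix")
}

#' @export
print.mirna_matrix <- function(x, ...) {
  cat("<mirna_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " probes (with detection p-values)\n", sep = "")
  invisible(x)
}

#' @export
dim.mirna_matrix <- function(x) dim(x$values)

# internal: coerce a feature input (matrix or container) to samples x features
feature_values <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$dosage)
  if (inherits(x, "expression_matrix")) return(x$values)
  if (inherits(x, "mirna_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  abort("features must be a matrix or a pgxscan matrix container")
}
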