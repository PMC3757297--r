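#' Three-way SNP-expression-phenotype triangulation
#'
#' Seeds on SNPs whose phenotype association passes `t_snp_auc`, scans each
#' seed SNP against all expression probes (the eQTL leg, restricted to seed
#' SNPs for fidelity and tractability), keeps SNP-probe pairs with eQTL p
#' below `t_snp_expr`, and retains those whose probe is itself associated with
#' the phenotype at `t_expr_auc`. All three legs are evaluated on the shared
#' sample cohort of the inputs.
#'
#' @param snp_auc association table from [pearson_scan()] of SNPs vs phenotype.
#' @param expr_auc association table of expression probes vs the phenotype.
#' @param genotypes a [genotype_matrix()] (dosages for the eQTL leg).
#' @param expression an adjusted [expression_matrix()].
#' @param thresholds numeric length-3: p cutoffs for the SNP-phenotype,
#'   SNP-expression and expression-phenotype legs (defaults 1e-4, 1e-4, 1e-3).
#' @param drug optional drug label carried into the output.
#' @return tibble of surviving pairs: `snp_id`, `snp_gene`, `probe_id`,
#'   `gene`, the three `r`/`p` leg statistics, `drug`.
#' @export
triangulate <- function(snp_auc, expr_auc, genotypes, expression,
                        thresholds = c(1e-4, 1e-4, 1e-3), drug = NA_character_) {
  if (length(thresholds) != 3 || any(thresholds <= 0) || any(thresholds >= 1)) {
    abort("`thresholds` must be three p-value cutoffs in (0, 1)")
  }
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"))
  seeds <- snp_auc |> filter(p < thresholds[1])
  empty <- tibble(snp_id = character(), snp_gene = character(),
                  probe_id = character(), gene = character(),
                  snp_auc_r = numeric(), snp_auc_p = numeric(),
                  snp_expr_r = numeric(), snp_expr_p = numeric(),
                  expr_auc_r = numeric(), expr_auc_p = numeric(),
                  drug = character())
  if (nrow(seeds) == 0) return(empty)

  probe_meta <- expression$probes
  snp_meta <- genotypes$snps
  expr_leg <- expr_auc |> select(probe_id = feature_id, expr_auc_r = r, expr_auc_p = p)

  pairs <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    sid <- seeds$feature_id[i]
    g <- genotypes$dosage[, sid]
    eqtl <- pearson_scan(expression, setNames(g, rownames(genotypes$dosage)),
                         kind = "probe", qvalues = FALSE)
    eqtl <- eqtl |> filter(p < thresholds[2])
    if (nrow(eqtl) == 0) return(NULL)
    tibble(snp_id = sid,
           probe_id = eqtl$feature_id,
           snp_auc_r = seeds$r[i], snp_auc_p = seeds$p[i],
           snp_expr_r = eqtl$r, snp_expr_p = eqtl$p)
  })
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  pairs |>
    inner_join(expr_leg, by = "probe_id") |>
    filter(expr_auc_p < thresholds[3]) |>
    left_join(snp_meta |> select(snp_id, snp_gene = gene), by = "snp_id") |>
    left_join(probe_meta |> select(probe_id, gene), by = "probe_id") |>
    mutate(drug = drug) |>
    select(snp_id, snp_gene, probe_id, gene, snp_auc_r, snp_auc_p,
           snp_expr_r, snp_expr_p, expr_auc_r, expr_auc_p, drug) |>
    arrange(snp_auc_p, snp_expr_p)
}

#' Intersect triangulated pairs across two drugs
#'
#' @param pairs_drug_a,pairs_drug_b outputs of [triangulate()] for two drugs.
#' @return tibble of (snp_id, probe_id) pairs present in both, with each
#'   drug's leg statistics suffixed by the drug label (or `_a`/`_b`).
#' @export
overlap_across_drugs <- function(pairs_drug_a, pairs_drug_b) {
  lab <- c(unique(pairs_drug_a$drug), unique(pairs_drug_b$drug))
  suff <- if (length(lab) == 2 && !anyNA(lab) && lab[1] != lab[2]) {
    paste0("_", tolower(lab))
  } else {
    c("_a", "_b")
  }
  inner_join(pairs_drug_a |> select(-drug), pairs_drug_b |> select(-drug),
             by = c("snp_id", "snp_gene", "probe_id", "gene"), suffix = suff)
}

#' Select candidate genes from the association panels
#'
#' Implements the three-panel selection strategy. Expression panel: probes
#' associated at `p_strong` in both drugs, plus probes at `p_extreme` in
#' either drug, plus genes carrying two probes each below `p_strong` in one
#' drug; probes failing the low-expression mask are ineligible, and probe
#' hits collapse to gene symbols (unannotated probes propagate under their
#' probe id). SNP panel: genes with two or more SNPs below `p_strong` in each
#' drug (gene present in both drugs' lists) and expressed in the cohort, plus
#' genes hosting a nonsynonymous SNP below `p_strong` in either drug.
#' Integrated panel: both the eQTL target genes and the SNP host genes of the
#' cross-drug triangle overlap, plus any `manual` additions (each requiring a
#' justification string).
#'
#' @param expr_assoc named list (one per drug) of probe association tables.
#' @param snp_assoc named list (one per drug) of SNP association tables.
#' @param triangles output of [overlap_across_drugs()].
#' @param em the raw (log2) [expression_matrix()] used for the low-expression
#'   mask and the "expressed gene" check.
#' @param snp_meta SNP metadata tibble (`snp_id`, `gene`, `func_class`).
#' @param p_strong,p_extreme p-value cutoffs (defaults 1e-4, 1e-5; strict).
#' @param expr_threshold linear-scale expression cutoff (default 50).
#' @param manual optional tibble `gene`, `justification` of analyst additions.
#' @return tibble `gene`, `panel`, `rule`, `drug`, `feature_id`, `p` (one row
#'   per triggering piece of evidence), sorted by panel then gene.
#' @export
select_candidates <- function(expr_assoc, snp_assoc, triangles, em, snp_meta,
                              p_strong = 1e-4, p_extreme = 1e-5,
                              expr_threshold = 50, manual = NULL) {
  stopifnot(is.list(expr_assoc), is.list(snp_assoc), length(expr_assoc) == 2,
            length(snp_assoc) == 2)
  drugs <- names(expr_assoc)
  mask <- low_expression_mask(em, expr_threshold)
  probe_gene <- em$probes |> select(probe_id, gene) |>
    mutate(gene = ifelse(is.na(gene), probe_id, gene))
  eligible <- mask$probe_id[!mask$masked]

  expr_hits <- purrr::map_dfr(drugs, function(d) {
    expr_assoc[[d]] |>
      filter(feature_id %in% eligible) |>
      select(probe_id = feature_id, p) |>
      mutate(drug = d)
  }) |> left_join(probe_gene, by = "probe_id")

  strong <- expr_hits |> filter(p < p_strong)
  both_drugs <- strong |>
    distinct(probe_id, gene, drug) |>
    count(probe_id, gene) |>
    filter(n == 2) |>
    select(probe_id, gene)
  rule_overlap <- strong |>
    semi_join(both_drugs, by = "probe_id") |>
    mutate(panel = "expression", rule = "overlap_both_drugs")
  rule_extreme <- expr_hits |>
    filter(p < p_extreme) |>
    mutate(panel = "expression", rule = "p_lt_1e-5_single_drug")
  rule_two_probes <- strong |>
    group_by(gene, drug) |>
    filter(dplyr::n_distinct(probe_id) >= 2) |>
    ungroup() |>
    mutate(panel = "expression", rule = "two_probes_one_gene")
  expr_panel <- bind_rows(rule_overlap, rule_extreme, rule_two_probes) |>
    select(gene, panel, rule, drug, feature_id = probe_id, p)

  meta_cols <- intersect(c("snp_id", "gene", "func_class"), names(snp_meta))
  snp_hits <- purrr::map_dfr(drugs, function(d) {
    snp_assoc[[d]] |>
      filter(p < p_strong) |>
      select(snp_id = feature_id, p) |>
      mutate(drug = d)
  }) |> left_join(snp_meta |> select(dplyr::all_of(meta_cols)), by = "snp_id")
  if (!"gene" %in% names(snp_hits)) snp_hits$gene <- NA_character_

  expressed_genes <- unique(probe_gene$gene[probe_gene$probe_id %in% eligible])
  multi_per_drug <- snp_hits |>
    filter(!is.na(gene)) |>
    group_by(drug, gene) |>
    filter(dplyr::n_distinct(snp_id) >= 2) |>
    ungroup()
  multi_genes <- multi_per_drug |>
    distinct(gene, drug) |>
    count(gene) |>
    filter(n == 2) |>
    pull(gene)
  rule_multi <- multi_per_drug |>
    filter(gene %in% multi_genes, gene %in% expressed_genes) |>
    mutate(panel = "snp", rule = "multi_snp_gene")
  rule_nonsyn <- snp_hits |>
    (\(x) {
      if (!"func_class" %in% names(x) || all(is.na(x$func_class))) {
        warn("no functional-class annotation; nonsynonymous rule skipped")
        x[0, ]
      } else {
        filter(x, func_class == "nonsynonymous")
      }
    })() |>
    mutate(panel = "snp", rule = "nonsynonymous_snp")
  snp_panel <- bind_rows(rule_multi, rule_nonsyn) |>
    select(gene, panel, rule, drug, feature_id = snp_id, p)

  int_panel <- tibble(gene = character(), panel = character(), rule = character(),
                      drug = NA_character_, feature_id = character(), p = numeric())
  if (!is.null(triangles) && nrow(triangles)) {
    tgt <- triangles |>
      mutate(gene = ifelse(is.na(gene), probe_id, gene)) |>
      select(gene, feature_id = probe_id) |>
      mutate(panel = "integrated", rule = "triangle_overlap",
             drug = NA_character_, p = NA_real_)
    host <- triangles |>
      filter(!is.na(snp_gene)) |>
      select(gene = snp_gene, feature_id = snp_id) |>
      mutate(panel = "integrated", rule = "triangle_overlap",
             drug = NA_character_, p = NA_real_)
    int_panel <- bind_rows(tgt, host) |>
      select(gene, panel, rule, drug, feature_id, p)
  }
  if (!is.null(manual) && nrow(manual)) {
    if (!all(c("gene", "justification") %in% names(manual)) ||
        any(!nzchar(manual$justification))) {
      abort("manual additions need `gene` and a nonempty `justification`")
    }
    int_panel <- bind_rows(int_panel,
                           tibble(gene = manual$gene, panel = "integrated",
                                  rule = "manual", drug = NA_character_,
                                  feature_id = manual$justification, p = NA_real_))
  }

  bind_rows(expr_panel, snp_panel, int_panel) |>
    distinct() |>
    arrange(factor(panel, c("expression", "snp", "integrated")), gene, rule, drug)
}

#' Summarise a candidate table to one row per gene and panel
#'
#' @param candidates output of [select_candidates()].
#' @return tibble `gene`, `panel`, `rules` (collapsed), `n_features`, `best_p`.
#' @export
summarise_candidates <- function(candidates) {
  candidates |>
    group_by(gene, panel) |>
    summarise(rules = paste(sort(unique(rule)), collapse = ";"),
              n_features = dplyr::n_distinct(feature_id),
              best_p = ifelse(all(is.na(p)), NA_real_, min(p, na.rm = TRUE)),
              .groups = "drop") |>
    arrange(factor(panel, c("expression", "snp", "integrated")), gene)
}

#' MicroRNA association screen
#'
#' Per drug, flags microRNA probes reaching Bonferroni-corrected genome-wide
#' significance (`alpha / m` with `m` the number of tested probes). Each
#' flagged microRNA is then correlated against the phenotype-associated
#' expression probes (probes below `p_strong` in either drug), keeping
#' microRNA-probe pairs below `p_strong`; negative pairs are repression-like.
#'
#' @param mirna_assoc named list (one per drug) of microRNA association tables.
#' @param expr_assoc named list (one per drug) of probe association tables.
#' @param expression adjusted [expression_matrix()].
#' @param mirna adjusted [mirna_matrix()] (values used as the pairing signal).
#' @param alpha family-wise error rate for the Bonferroni flag (default 0.05).
#' @param p_strong p cutoff for both pairing legs (default 1e-4).
#' @return list with `associations` (per-drug table with `bonferroni_p` and
#'   `flagged`), `threshold` (the [bonferroni_threshold()] result), and
#'   `pairs` (tibble `mirna_id`, `probe_id`, `gene`, `r`, `p`).
#' @export
mirna_screen <- function(mirna_assoc, expr_assoc, expression, mirna,
                         alpha = 0.05, p_strong = 1e-4) {
  stopifnot(is.list(mirna_assoc), length(mirna_assoc) >= 1)
  drugs <- names(mirna_assoc)
  m <- length(unique(unlist(lapply(mirna_assoc, function(x) x$feature_id))))
  thr <- bonferroni_threshold(alpha, m)
  assoc <- purrr::map_dfr(drugs, function(d) {
    mirna_assoc[[d]] |>
      mutate(drug = d, bonferroni_p = bonferroni_adjust(p, m),
             flagged = p < thr$threshold)
  }) |> select(drug, feature_id, kind, n_used, r, p, q, bonferroni_p, flagged)

  flagged <- unique(assoc$feature_id[assoc$flagged])
  target_probes <- unique(unlist(lapply(expr_assoc, function(x) {
    x$feature_id[x$p < p_strong]
  })))
  pairs <- tibble(mirna_id = character(), probe_id = character(),
                  gene = character(), r = numeric(), p = numeric())
  if (length(flagged) && length(target_probes)) {
    probe_gene <- expression$probes |> select(probe_id, gene)
    sub <- expression$values[, target_probes, drop = FALSE]
    pairs <- purrr::map_dfr(flagged, function(mid) {
      y <- setNames(mirna$values[, mid], rownames(mirna$values))
      sc <- pearson_scan(sub, y, kind = "probe", qvalues = FALSE)
      sc |> filter(p < p_strong) |>
        mutate(mirna_id = mid) |>
        select(mirna_id, probe_id = feature_id, r, p)
    })
    if (nrow(pairs)) {
      pairs <- pairs |> left_join(probe_gene, by = "probe_id") |>
        select(mirna_id, probe_id, gene, r, p)
    }
  }
  list(associations = assoc, threshold = thr, pairs = pairs)
}
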