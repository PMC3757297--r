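# pgxscan

Pharmacogenomic association scans on cell-line cytotoxicity phenotypes.

`pgxscan` is an R package for the classic lymphoblastoid cell-line (LCL)
pharmacogenomics design: a panel of a few hundred genotyped, expression- and
microRNA-profiled cell lines is exposed to a drug over a log-spaced dose
range, a per-line drug-sensitivity phenotype is derived from the viability
curve, and every genomic feature is scanned for association with that
phenotype. It is aimed at statistical geneticists and computational
pharmacologists who want the whole chain — curve fitting, phenotype
transformation, QC, stratification correction, correlation scans, FDR, and
multi-omic candidate selection — as tested, composable functions rather than
one-off analysis scripts.

## The model and statistics

**Phenotype.** Each cell line's viability (fraction of control) at dose *d*
is modelled by a four-parameter logistic in log dose,

    f(d) = b + (t − b) / (1 + 10^{h (log10 d − e)}),

with lower/upper asymptotes *b*, *t*, location *e* = log10 IC50, and slope
*h*. Three family members are fit per line (free; top fixed at 1; bottom
fixed at 0) and the best is chosen by small-sample corrected AIC, ties to
fewer parameters. The phenotype is the area under the fitted curve over
doses 10⁻⁷ nM – 1 µM (trapezoidal, log10-dose scale), so a fully resistant
flat line scores 10 and lower AUC means a more sensitive line.

**Preprocessing.** AUC is van der Waerden transformed
(Φ⁻¹(rank/(n+1))), residualized on sex, race and the top genotype principal
components (EIGENSTRAT-style standardized dosages), and standardized. SNPs
pass call-rate ≥ 0.95, MAF ≥ 0.05 and exact-test HWE p ≥ 0.001; expression is
residualized on sex/race/batch; microRNA probes pass a detection/missingness/
variability cascade (detection p < 0.01; probe missingness < 80%; sample
missingness < 50%; SD ≥ 0.40).

**Association.** Pearson correlation r per feature, two-sided p from
t = r√(n−2)/√(1−r²) with n−2 df, Storey q-values (smoothed π̂₀), and
Bonferroni thresholds for genome-wide significance.

**Integration.** SNPs associated with the phenotype (p < 10⁻⁴) are scanned
against expression (eQTL leg, p < 10⁻⁴) and retained when the target probe is
itself phenotype-associated (p < 10⁻³); triangles overlapping across the two
drugs, probe-level selection rules (both-drug overlap at 10⁻⁴, single-drug
10⁻⁵, two probes per gene, multi-SNP genes, nonsynonymous SNPs) and a
Bonferroni-flagged microRNA screen yield the candidate gene panels.

A synthetic-data generator (`simulate_study()`) emulates the study design —
three ancestry groups (87/91/94 lines) with Balding–Nichols allele-frequency
divergence, log2 expression with sex/race/batch structure, bead-array
microRNA intensities with detection p-values, 8-dose viability curves — with
planted, recorded effects so every stage can be tested against ground truth.

## Worked example

```r
library(pgxscan)
study <- simulate_study(sim_config(seed = 1))   # 272 lines, 2 drugs
auc <- derive_auc_phenotypes(study$dose_response)
head(auc, 3)
#>   sample_id drug         auc variant      converged
#> 1 LCL001    Everolimus  9.89 BOTTOM_FIXED TRUE
#> 2 LCL001    Rapamycin   9.92 BOTTOM_FIXED TRUE
#> 3 LCL002    Everolimus  9.49 TOP_FIXED    TRUE
```

LCL001 is resistant to both drugs (AUC near the ceiling of 10). Running the
whole pipeline on the written study recovers exactly the planted candidate
structure:

```r
dir <- file.path(tempdir(), "study"); write_study(study, dir)
res <- run_pipeline(run_config(input_dir = dir))
res$candidate_summary
#>    gene    panel      rules                              n_features   best_p
#>  1 EXP2P   expression overlap_both_drugs;p_lt_1e-5_...            2 1.34e- 7
#>  2 EXPA    expression overlap_both_drugs;p_lt_1e-5_...            1 3.17e-11
#>  ...
#>  7 SNPM    snp        multi_snp_gene                              2 3.67e-16
#>  8 SNPNS   snp        nonsynonymous_snp                           1 4.40e- 8
#>  ...
#> 14 TRIHOST integrated triangle_overlap                            1 NA
res$mirna_screen$pairs
#>   mirna_id probe_id   gene       r        p
#> 1 mir_001  probe_0003 EXPC  -0.430 4.26e-13
#> 2 mir_001  probe_0001 EXPA  -0.380 2.57e-10
#> 3 mir_001  probe_0002 EXPB  -0.377 3.60e-10
```

Every planted gene appears in its intended panel (`EXPA`–`EXPD`, `EXP2P` and
the eQTL target `TRITGT` in the expression panel; the two-SNP gene `SNPM` and
nonsynonymous-SNP gene `SNPNS` in the SNP panel; the triangle target and host
in the integrated panel), the planted microRNA is genome-wide significant for
both drugs, and its three repression targets are reported with negative
correlations. `autoplot()` on a `logistic_fit`, `plot_manhattan()` and
`plot_auc_distribution()` give the standard figures; `tidy()`/`glance()`
return curve parameters and fit summaries.

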