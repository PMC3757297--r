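Package: pgxscan
Title: Pharmacogenomic Association Scans on Cell-Line Cytotoxicity Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for cell-line pharmacogenomic association mapping.
    Derives area-under-the-curve (AUC) cytotoxicity phenotypes from
    dose-response viability data by fitting a family of four-parameter
    logistic models, applies rank-normal (van der Waerden) transformation
    and covariate/stratification adjustment, runs genome-wide Pearson
    correlation scans of SNPs, mRNA probes and microRNA probes against the
    phenotype with Storey q-values, triangulates SNP-expression-phenotype
    evidence, and selects candidate genes by a reproducible rule set.
    Includes a synthetic-data generator with planted effects so every stage
    has a ground-truth test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
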