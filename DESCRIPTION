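Package: seropanel
Title: Serum Proteomics Biomarker Panel Discovery and Targeted Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seeded and fully tested pipeline for label-free
    serum proteomics biomarker discovery and selected-reaction-monitoring (SRM)
    verification in matched case/control designs. Implements MaxQuant-style
    protein-group table ingestion with identification filtering, log2
    transformation, left-censored (missing-not-at-random) imputation from a
    downshifted normal distribution and technical-replicate averaging;
    differential abundance testing with a reproducibility-optimized family of
    t-type statistics and permutation-based p-values and false discovery rates;
    biomarker panel selection by repeated cross-validated L1-penalized logistic
    regression with within-fold prescreening, scored by AUROC with DeLong
    variance estimates, confidence intervals and paired comparisons; and SRM
    verification via light/heavy transition ratios, housekeeping normalization,
    Tukey median-polish protein summarization and group comparison with
    multiplicity adjustment. A synthetic-data module generates discovery and
    SRM data sets with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    glmnet,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
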