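Package: adipopanel
Title: Adipokine Diagnostic-Panel Discovery for Obese Type 2 Diabetes Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering diagnostic biomarker panels in obese
    type-2-diabetes cohorts measured before and after metformin therapy.
    Computes derived clinical indices (HOMA, QUICKI, eGDR, MDRD eGFR, ACR,
    TG/HDL) under strict unit contracts, simulates synthetic clinical cohorts
    with prescribed marginal distributions, Spearman correlation targets and
    paired treatment effects via a Gaussian copula, provides the descriptive
    and gated inferential statistics layer (Shapiro-Wilk/Levene gating into
    t, Mann-Whitney, paired t or Wilcoxon tests; Spearman correlation tables;
    percent-change analyses), fits a Mahalanobis-distance linear discriminant
    classifier with a stratified 2/3-1/3 learning/test split, and runs
    exhaustive combinatorial panel searches ranked by classification accuracy
    with minimal-panel selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    Matrix,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
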