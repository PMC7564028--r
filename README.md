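# adipopanel

Diagnostic-panel discovery for obese type-2-diabetes (T2DM) cohorts.

Obese patients with newly diagnosed T2DM and obese, metabolically healthy
controls overlap on any single routine measurement. This package asks
which *small set* of biochemical variables — plasma adipokines (adropin,
irisin, vaspin) together with insulin-resistance, renal and
lipid-carbohydrate indicators — jointly separates (a) healthy obesity
from obese T2DM and (b) the metabolic state of the same patients before
vs after six months of metformin. It is aimed at biostatisticians and
clinical-chemistry researchers prototyping panel-selection analyses.

## What it implements

* **Derived clinical indices** with strict unit contracts:
  HOMA1-IR = I·G/405, HOMA1 %B = 360·I/(G−63), %S = 100/HOMA-IR,
  QUICKI = 1/(log₁₀I + log₁₀G),
  eGDR = 24.31 − 12.22·WHR − 3.29·htn − 0.57·HbA1c (mg/kg/min, < 7.5
  flags insulin resistance), 4-variable MDRD eGFR, urinary
  albumin/creatinine ratio, TG/HDL, BMI.
* **Synthetic cohorts**: a Gaussian-copula generator
  (`simulate_cohort()`, `default_spec()`) reproducing the study
  structure — 20 controls (11F/9M), 40 patients (24F/16M) at baseline
  and month 6 — with printed mean±SD / median(IQR) marginals, targeted
  Spearman correlations (latent Pearson r = 2 sin(πρ/6)), within-patient
  pairing, and treatment effects encoded as per-visit marginals.
* **Cohort statistics**: mean±SD / median(IQR) summaries, percent change
  following therapy, Shapiro-Wilk/Levene-gated t vs Mann-Whitney and
  paired t vs Wilcoxon tests, Spearman correlation tables, per-patient
  percent-change correlations.
* **Mahalanobis discriminant classification**: class centroids, pooled
  within-class covariance Σ, assignment by arg min (x−μ)ᵀΣ⁻¹(x−μ),
  stratified 2/3 learning / 1/3 test split (round-half-up per class,
  subject-level to prevent leakage), ACC = (TP+TN)/(TP+TN+FP+FN).
* **Exhaustive panel search**: all 2ᵏ−1 variable subsets (16383 for the
  default 14 candidates) or all subsets containing anchor variables, on
  one shared split; accuracy ranking, cumulative-max accuracy curve,
  Pareto front, and minimal-panel selection.

## Worked example

```r
library(adipopanel)

cohort <- simulate_cohort(default_spec(), seed = 42)  # 100 subject-visits
data   <- add_indices(cohort)                         # + derived indices

# Do the three adipokines separate healthy obesity from T2DM?
evaluate_panel(data, c("adropin", "irisin", "vaspin"),
               task = "healthy_vs_t2dm", seed = 42)
#>                   panel      acc tp tn fp fn n_learning n_test
#> 1 adropin,irisin,vaspin 75.75758 20  5  2  6         67     33
```

75.8% of the 33 held-out subject-visits are classified correctly
(20 true T2DM, 5 true controls); chance would be near the 24/33 majority
rate, and 2/3 of the data (67 rows, split by subject) trained the model.

```r
# Exhaustive search over six candidates for the metformin-response task
search <- exhaustive_search(data,
  c("vaspin", "irisin", "hba1c", "ldl", "insulin", "egdr"),
  task = "pre_vs_post", seed = 42)
search
#> <panel_search_report> task: pre_vs_post | mode: unanchored | 63 panels evaluated
#>  best panel: vaspin,irisin,hba1c,insulin (ACC = 88.5%)

head(search$ranking[, c("panel", "size", "acc")], 3)
#>                             panel size      acc
#> 1     vaspin,irisin,hba1c,insulin    4 88.46154
#> 2                      irisin,ldl    2 84.61538
#> 3 vaspin,irisin,hba1c,ldl,insulin    5 84.61538

minimal_panels(search, 75)[, c("panel", "size", "acc")]
#>    panel size      acc
#> 1 irisin    1 80.76923
```

All 2⁶−1 = 63 subsets of the six candidates are fitted on one shared
split: the best panel classifies 88.5% of held-out visits as pre- or
post-treatment, and a single variable (irisin, whose level roughly
triples on therapy in this cohort) already reaches the 75% floor with
the minimal panel size.

```r
# Gated two-group comparison, control vs pre-treatment irisin
compare_independent(
  data$irisin[data$group == "control"],
  data$irisin[data$group == "t2dm" & data$visit == "baseline"],
  variable = "irisin")
#>   variable    test_used statistic      p_value significant
#> 1   irisin mann_whitney       178 0.0003426391        TRUE
```

The skewed adipokine fails the Shapiro-Wilk gate, so the comparison
routes to a Mann-Whitney U test, which finds the group difference the
generator planted.

The full pipeline (cohort → indices → summary tables → correlation
tables → three-parameter suite → exhaustive search, all artifacts plus a
manifest in one run directory) is `run_full_pipeline("run_dir", seed =
42)`; a thin command-line wrapper lives at `inst/cli/adipopanel.R`.

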