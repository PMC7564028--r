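---
title: "Methods: synthetic cohorts, Mahalanobis panels, and the adipopanel pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, Mahalanobis panels, and the adipopanel pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipopanel)
```

## The problem

Obese patients with newly diagnosed type 2 diabetes (T2DM) and obese,
metabolically healthy controls overlap heavily on any single routine
biochemical measurement. Plasma adipokines and regulatory peptides —
adropin, irisin and vaspin — carry complementary information about adipose
tissue state, insulin resistance and treatment response, which suggests
asking two classification questions:

1. which *small panel* of variables best separates metabolically healthy
   obesity from obese T2DM, and
2. which panel best separates the metabolic state of the same patients
   before and after six months of metformin monotherapy.

`adipopanel` implements that analysis end to end: derived clinical
indices, cohort summary and inference statistics, a Mahalanobis-distance
discriminant classifier with a stratified learning/test split, and an
exhaustive search over all variable subsets ranked by test accuracy. A
synthetic-cohort generator reproduces the statistical structure of the
study population so the whole pipeline is testable without patient data.

## Derived clinical indices

All index functions are pure, vectorised, and enforce strict unit
contracts (insulin in uU/mL, glucose in mg/dL, creatinine in mg/dL,
urinary albumin in ug/mL):

* **BMI** = weight / height² (kg/m²).
* **HOMA1-IR** = insulin x glucose / 405 (dimensionless); the classical
  single-equation homeostasis model.
* **HOMA1 %B** = 360 x insulin / (glucose − 63), undefined at glucose <=
  63 mg/dL (the model's fasting-glucose asymptote); **HOMA1 %S** =
  100 / HOMA-IR.
* **QUICKI** = 1 / (log₁₀ insulin + log₁₀ glucose). The logarithm base is
  configurable but defaults to 10, the base of the original definition;
  natural logs would change the index scale, not its ordering.
* **eGDR** (mg/kg/min) = 24.31 − 12.22 WHR − 3.29 htn − 0.57 HbA1c, a
  clamp-calibrated linear surrogate. The raw value is returned without
  clipping at zero — the formula is linear and consumers may want the
  tail. Values < 7.5 mg/kg/min flag reduced insulin sensitivity
  (`ir_flag()`, strict inequality).
* **eGFR** by the 4-variable MDRD equation,
  175 x sCr^−1.154 x age^−0.203 x 1.212(black) x 0.742(female).
* **ACR** = urinary albumin (ug/mL) x 100 / urinary creatinine (mg/dL),
  the factor 100 converting creatinine to mg/mL so the ratio lands on the
  conventional ug albumin / mg creatinine scale.
* **TG/HDL**, an indirect insulin-resistance surrogate.

### Two HOMA families, two column names

Clinical studies frequently report HOMA values from the Oxford HOMA2
calculator, a closed physiological model that cannot be recomputed from
fasting insulin and glucose alone. The package therefore keeps two
families strictly apart:

* `homa_ir`, `homa_b`, `homa_s` — *calculator-style* values. In synthetic
  cohorts these are generated directly from their summary distributions
  and treated as primary measurements (with %S emitted as exactly
  100/HOMA-IR, which is its definition in both HOMA families).
* `homa1_ir`, `homa1_b`, `homa1_s` — the classical single-equation
  surrogates computed by `add_indices()` from insulin and glucose.

The two families differ numerically; neither is asserted to equal the
other anywhere in the pipeline.

### Missing data

`compute_index_set()` computes every index it can and records a reason
code per missing index ("missing: insulin", "glucose <= 63", ...). No
imputation happens anywhere; downstream stages use complete cases per
analysis.

## The synthetic-cohort generator

`default_spec()` encodes the emulated study conditions: 20 obese
non-diabetic controls (11F/9M) and 40 obese newly diagnosed T2DM patients
(24F/16M), patients measured at baseline and after six months of
metformin. Each generated variable carries a marginal distribution per
stratum (control / patient baseline / patient month 6) taken from the
printed summary tables, so the per-visit summaries and the percent-change
column are generator parameters, not fitted quantities.

**Marginal families.** Near-symmetric variables (glucose, HbA1c, blood
pressure, lipoproteins, anthropometrics, serum creatinine) are normal
with the printed mean and SD; draws at or below zero are redrawn from the
positive tail, a negligible-mass event for every default variable.
Clearly right-skewed positive variables — triglycerides, urinary
creatinine and albumin, insulin, and the calculator-style HOMA columns,
all with printed mean/SD ratios below 3 — use *moment-matched
log-normals* (`lognormal_from_mean_sd()`): the printed mean and SD are
reproduced exactly and no truncation is needed. A truncated normal for
these would inflate the recovered means by far more than the sampling
error the fidelity tests allow. The three plasma adipokines are
log-normal from the printed median and interquartile range
(`lognormal_from_median_iqr()`): the log-scale mean is the log median and
the log-scale SD is ln(q3/q1)/(2 z₀.₇₅), which matches the median exactly
and the IQR in the geometric-symmetric sense (the q3/q1 ratio is exact;
individual quartiles are approximated when the printed quartiles are
asymmetric about the median). Adropin in controls carries a sex-specific
marginal from the printed male and female medians.

**Dependence.** A Gaussian copula realises stratum-specific Spearman
correlation targets: a latent Pearson correlation of 2 sin(pi rho / 6)
yields Spearman rho after any monotone marginal transform. Targets are
the statistically significant cells of the study's correlation tables;
cells printed against a derived index are attached to their monotone raw
driver (eGFR falls with serum creatinine, QUICKI falls with insulin, so
those targets flip sign onto scr and insulin; the weight cell rides on
BMI). A small set of *structural* background correlations (lipid
interrelations, insulin–HOMA coherence, systolic–diastolic pressure)
keeps the joint distribution physiologically plausible and — importantly
— jointly feasible: with a strong insulin/HOMA-IR link, setting every
non-significant cell to exactly zero produces an indefinite target
matrix, so two printed non-significant month-6 cells (vaspin–HOMA-IR
0.349, irisin–HOMA-IR −0.087) are retained at their printed values
instead of being zeroed. Any remaining infeasibility is repaired with
`Matrix::nearPD` under a warning; the shipped default spec is positive
definite without repair.

**Pairing and treatment effects.** A patient's month-6 latent vector is
a mixture a·Z_baseline + sqrt(1−a²)·E with a chosen so the same-variable
across-visit Spearman correlation equals the spec's `pairing` (default
0.7), and E drawn with the month-6 correlation structure. Treatment
effects need no separate machinery: each variable's month-6 marginal *is*
the printed post-treatment summary, so mean differences and median ratios
match the printed percent changes by construction. One consequence worth
knowing: realized month-6 *cross-sectional* correlations are a mixture of
the baseline and month-6 structures (weights a² and 1−a²), so month-6
targets are attenuated toward baseline values; baseline targets are
realized exactly. Sex, height and the hypertension flag are constant per
subject; age advances by the visit interval; weight is BMI x height²
with height ~ N(1.68, 0.07) m; hypertension is Bernoulli per subject
(prevalence 0.4 in controls, 0.7 in patients — free parameters, the
study prints no prevalence).

**What the generator does not emulate.** Assay measurement error and
detection limits; joint tail behaviour beyond a Gaussian copula;
consistency between generated calculator-style HOMA columns and the raw
insulin/glucose they would imply; the printed summaries of *derived*
indices (the generated WHR/hypertension/HbA1c values imply an eGDR
distribution close to, but not exactly, the printed one — the printed
eGDR mean is consistent with a near-normotensive control group, while the
generator keeps its stated prevalence parameters). Passing fidelity tests
therefore demonstrates that the pipeline recovers the structure the
generator encodes, not that it would behave identically on real patients.

## The statistics layer

* `summarize_values()` gives mean ± SD (n−1 denominator) or median with
  25th/75th percentiles (type-7 quantiles).
* `percent_change(before, after)` = 100 (after − before)/before,
  presentation-rounded to 2 decimals. Table-style percent change is
  computed from the two group-level summary cells; `delta_correlations()`
  instead computes *per-patient* percent changes and Spearman-correlates
  adipokine changes with metabolic-parameter changes. The two conventions
  answer different questions and are never conflated.
* `compare_independent()` gates with Shapiro-Wilk normality in each group
  and Levene's test (median-centred, via `car::leveneTest`) for variance
  homogeneity, both at 0.05 (configurable): pass → pooled-variance
  Student t; fail → Mann-Whitney U (`stats::wilcox.test` conventions:
  exact for small tie-free samples, normal approximation with continuity
  correction otherwise). `compare_paired()` gates on Shapiro-Wilk of the
  paired differences into a paired t or Wilcoxon signed-rank test.
  All-zero differences are a degenerate design and raise an error.
* Raw p-values throughout; the emulated analysis reports no
  multiple-testing correction, and the package follows it (documented
  deliberately).
* Spearman correlations use `stats::cor.test(method = "spearman",
  exact = FALSE)`; cells with fewer than 3 complete cases are flagged
  "insufficient n" rather than dropped silently.

## Mahalanobis discriminant classification

The classifier is deliberately minimal, matching the described analysis:
class centroids plus a pooled within-class covariance
Σ = ((n₁−1)S₁ + (n₂−1)S₂)/(N−2); an observation goes to the class with
the smaller squared Mahalanobis distance (x−μ)ᵀΣ⁻¹(x−μ). Equal priors (no
posterior/prior term), no feature standardisation (the distance is affine
invariant). Ties go deterministically to the first class.

* **Split.** Per class, round-half-up of 2N/3 units form the learning
  set, the rest the test set ((20, 40) → learning (13, 27), test
  (7, 13)). For healthy-vs-T2DM the patient class contains both visits of
  each patient, so splitting is done at the *subject* level — both rows
  of a patient land on the same side, preventing subject-level leakage.
  For pre-vs-post the two visits are the two classes and rows are split
  naively; the classifier deliberately ignores the within-patient
  pairing, mirroring the emulated protocol (a caveat, not an
  endorsement: a paired analysis would be more powerful).
* **Singularity.** If the pooled covariance's condition number exceeds
  1e10, a ridge ε = 1e-6 tr(Σ)/p is added before inversion — tiny panels
  on n ≈ 40 can be collinear (duplicated or linearly dependent indices).
  Zero-variance features are rejected by name.
* **Accuracy.** ACC = (TP+TN)/(TP+TN+FP+FN) on the held-out test set,
  reported as a percentage in tables.

## Exhaustive panel search

`exhaustive_search()` evaluates every non-empty subset of k candidate
variables (2^k − 1 panels) or, in anchored mode, every subset containing
a fixed anchor set (2^(k−a) panels). The default candidate list has 14
variables — vaspin plus 13 metabolic, renal and insulin-sensitivity
indicators — because the emulated study's cumulative-accuracy figure
counts 2^14 − 1 = 16383 classifications. That count is only consistent
with *unanchored* enumeration over all 14 (an always-present vaspin over
the other 13 would give 2^13); both modes are provided and the unanchored
mode is the default.

All panels share one split (same seed), so accuracy differences reflect
panels rather than split noise; `reseed_per_panel = TRUE` provides the
per-panel-resplit sensitivity mode. Enumeration follows binary counting
over the candidate list, which fixes the cumulative-maximum-accuracy
curve; ranking orders by accuracy (descending), then panel size
(ascending), then the lexicographic panel string, making reports
byte-reproducible. `minimal_panels()` returns the smallest panels at or
above an accuracy floor — the "fewest assays with the most
discrimination" selection rule. `three_parameter_suite()` evaluates the
fixed printed list of 16 three-variable panels (the adropin/irisin/vaspin
triple plus each adipokine crossed with five indicator pairs).

## Validation experiment sizes

The test suite validates the pipeline at sizes chosen to make each check
statistically meaningful while keeping the suite fast:

* **Generator fidelity** at n = 5000 per group: normal-family means and
  SDs within 3 standard errors; moment-matched log-normal means within 3
  SE and SDs within a kurtosis-corrected 3 SE; medians of the
  IQR-parameterized adipokines within 2%, estimated from 10 pooled
  replicate cohorts because a single cohort's median of a log-normal with
  log-SD ≈ 1.1 has a sampling SE of about 2% — pooling tests the
  generator rather than the median estimator's noise. Baseline Spearman
  targets recovered within ±0.05.
* **Null calibration**: a 3-variable pure-noise panel on balanced
  pre/post classes (24 + 24 rows, pairing 0), 200 seeds; mean test
  accuracy must sit in [45%, 55%].
* **Signal recovery**: all separation planted in exactly two of six
  candidates (2.5 SD shift, 150 patients). The top-ranked two-variable
  panel must be that pair in at least 90% of 50 seeds; the effect and
  sample size were set by a power calculation so the designed success
  probability (~98%) clears the requirement rather than straddling it.
* **Gated-test level**: 1000 null replications of the gated two-group
  comparison at n = 20 + 20; the empirical level must lie in
  [0.035, 0.065].
* **Oracle equivalence**: the classifier must agree exactly with a
  brute-force triple-loop evaluation (analytic 1x1/2x2 inverses) on an
  exhaustive grid of instances with ≤ 6 learning rows and ≤ 2 features.

## Known limitations

* The generated calculator-style HOMA columns are marginally and
  rank-correlation faithful but not functionally consistent with the raw
  insulin/glucose columns of the same row.
* Month-6 cross-sectional correlation targets are attenuated by the
  pairing mixture (see above).
* The pre-vs-post classifier treats visits as independent groups; its
  accuracy estimates inherit that design choice.
* Printed accuracies of the emulated study depend on its unavailable
  patient data; the package reproduces the *structure* of the analysis
  (counts, splits, statistics), and its accuracies on synthetic cohorts
  are not comparable to the printed ones.
* Single-imputation-free complete-case handling means panels with heavy
  missingness lose rows; the result row says so rather than guessing.
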