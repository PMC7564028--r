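# Generative description of a synthetic clinical cohort: per-variable
# marginal distributions by stratum (control / patient baseline / patient
# month 6), Spearman correlation targets per stratum, and the within-patient
# pairing of the two visits.

#' Log-normal parameters from a printed median and interquartile range
#'
#' Skewed clinical variables are often reported as median (25th-75th
#' percentile). Under a log-normal model the log-scale mean is the log
#' median and the log-scale SD is the log IQR width divided by twice the
#' standard-normal 75th-percentile deviate; the returned distribution has
#' the exact median, and the IQR is matched under geometric symmetry of the
#' quartiles.
#'
#' @param median,q1,q3 Printed median and quartiles; must satisfy
#'   `0 < q1 < median < q3`.
#' @return Named vector `c(meanlog, sdlog)`.
#' @examples
#' lognormal_from_median_iqr(0.12, 0.07, 0.29)
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!(is.finite(q1) && is.finite(median) && is.finite(q3)) ||
    q1 <= 0 || q1 >= median || median >= q3) {
    stop("need 0 < q1 < median < q3", call. = FALSE)
  }
  c(
    meanlog = log(median),
    sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75))
  )
}

#' Log-normal parameters matching a printed mean and SD
#'
#' Moment-matching for positive right-skewed variables reported as
#' mean +/- SD: the returned log-normal has exactly the requested first two
#' moments.
#'
#' @param mean,sd Target arithmetic mean and standard deviation (both > 0).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0) {
    stop("mean and sd must be positive", call. = FALSE)
  }
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Spearman-to-Pearson correlation conversion for a Gaussian copula
#'
#' A Gaussian copula with latent Pearson correlation `2 sin(pi rho / 6)`
#' realises Spearman rank correlation `rho` after any strictly monotone
#' marginal transform.
#'
#' @param rho Target Spearman correlation(s) in \[-1, 1\].
#' @return Latent Pearson correlation(s).
#' @export
spearman_to_pearson <- function(rho) {
  stopifnot(all(abs(rho) <= 1))
  2 * sin(pi * rho / 6)
}

# A marginal for one variable in one stratum. mean/sd kept for normal and
# moment-matched log-normal; median/q1/q3 for IQR-specified log-normals.
marginal <- function(family, ...) {
  p <- list(...)
  if (family == "normal") {
    stopifnot(p$sd > 0)
    list(family = "normal", mean = p$mean, sd = p$sd)
  } else if (family == "lognormal") {
    if (!is.null(p$median)) {
      lp <- lognormal_from_median_iqr(p$median, p$q1, p$q3)
      list(
        family = "lognormal", meanlog = lp[["meanlog"]], sdlog = lp[["sdlog"]],
        median = p$median, q1 = p$q1, q3 = p$q3
      )
    } else {
      lp <- lognormal_from_mean_sd(p$mean, p$sd)
      list(
        family = "lognormal", meanlog = lp[["meanlog"]], sdlog = lp[["sdlog"]],
        mean = p$mean, sd = p$sd
      )
    }
  } else {
    stop("unknown family: ", family, call. = FALSE)
  }
}

#' Declare one generated variable of a cohort specification
#'
#' @param name Variable (column) name.
#' @param family `"normal"` or `"lognormal"`.
#' @param control,baseline,month6 Per-stratum marginals built with the
#'   internal parameter lists, e.g. `list(mean = 90.5, sd = 5.09)` or
#'   `list(median = 0.12, q1 = 0.07, q3 = 0.29)`. A stratum may instead be
#'   a list with `F` and `M` entries to impose a sex-specific marginal.
#' @return A `variable_spec` list.
#' @export
variable_spec <- function(name, family, control, baseline, month6) {
  build <- function(p) {
    if (!is.null(p$F)) {
      list(
        F = do.call(marginal, c(family, p$F)),
        M = do.call(marginal, c(family, p$M))
      )
    } else {
      do.call(marginal, c(family, p))
    }
  }
  structure(
    list(
      name = name, family = family,
      strata = list(
        control = build(control),
        baseline = build(baseline),
        month6 = build(month6)
      )
    ),
    class = "variable_spec"
  )
}

#' Construct a cohort specification
#'
#' @param n_control,n_patient Group sizes (>= 2).
#' @param control_sex,patient_sex Named counts `c(F = ..., M = ...)`
#'   summing to the group size.
#' @param variables List of [variable_spec()] objects.
#' @param correlation_targets Tibble with columns `var_a`, `var_b`,
#'   `stratum` (control/baseline/month6) and `rho` (target Spearman).
#' @param structural Like `correlation_targets` but applied to every
#'   stratum: background physiological correlations that are not themselves
#'   calibration targets.
#' @param pairing Within-patient Spearman correlation of a variable across
#'   the two visits (default 0.7).
#' @param htn_prev Named hypertension prevalences `c(control=, t2dm=)`.
#' @param height Named `c(mean=, sd=)` of height in m (constant per
#'   subject; weight is derived as BMI x height^2).
#' @param age_drift Years added to baseline age at the month-6 visit.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_control = 20L, n_patient = 40L,
                        control_sex = c(F = 11L, M = 9L),
                        patient_sex = c(F = 24L, M = 16L),
                        variables = list(),
                        correlation_targets = empty_cor_targets(),
                        structural = empty_cor_targets(),
                        pairing = 0.7,
                        htn_prev = c(control = 0.4, t2dm = 0.7),
                        height = c(mean = 1.68, sd = 0.07),
                        age_drift = 0.6) {
  stopifnot(
    n_control >= 2, n_patient >= 2,
    sum(control_sex) == n_control, sum(patient_sex) == n_patient,
    pairing >= 0, pairing < 1
  )
  vn <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(vn)) stop("duplicated variable names", call. = FALSE)
  for (tab in list(correlation_targets, structural)) {
    bad <- setdiff(c(tab$var_a, tab$var_b), vn)
    if (length(bad)) {
      stop(
        "correlation target names not generated variables: ",
        paste(unique(bad), collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      n_control = as.integer(n_control), n_patient = as.integer(n_patient),
      control_sex = control_sex, patient_sex = patient_sex,
      variables = stats::setNames(variables, vn),
      correlation_targets = correlation_targets,
      structural = structural,
      pairing = pairing, htn_prev = htn_prev,
      height = height, age_drift = age_drift
    ),
    class = "cohort_spec"
  )
}

empty_cor_targets <- function() {
  tibble::tibble(
    var_a = character(), var_b = character(),
    stratum = character(), rho = numeric()
  )
}

cor_targets <- function(...) {
  rows <- list(...)
  tibble::tibble(
    var_a = vapply(rows, `[[`, character(1), 1),
    var_b = vapply(rows, `[[`, character(1), 2),
    stratum = vapply(rows, `[[`, character(1), 3),
    rho = vapply(rows, function(r) as.numeric(r[[4]]), numeric(1))
  )
}

#' Look up the summary cell a spec prescribes for one variable
#'
#' Returns the generator's target summary for a variable in a stratum:
#' `mean`/`sd` for normal and moment-matched log-normal marginals,
#' `median`/`q1`/`q3` for IQR-specified log-normals. These are the
#' before/after summary cells the percent-change columns are computed
#' from.
#'
#' @param spec A [cohort_spec()].
#' @param var Variable name.
#' @param stratum `"control"`, `"baseline"` or `"month6"`.
#' @param sex `"F"` or `"M"` when the marginal is sex-specific.
#' @return Named numeric vector of the summary cell.
#' @export
spec_cell <- function(spec, var, stratum, sex = NULL) {
  vs <- spec$variables[[var]]
  if (is.null(vs)) stop("unknown variable: ", var, call. = FALSE)
  m <- vs$strata[[stratum]]
  if (is.null(m$family)) {
    if (is.null(sex)) {
      stop("marginal for ", var, "/", stratum,
        " is sex-specific; pass sex = \"F\" or \"M\"",
        call. = FALSE
      )
    }
    m <- m[[sex]]
  }
  if (m$family == "normal" || !is.null(m[["mean"]])) {
    c(mean = m[["mean"]], sd = m[["sd"]])
  } else {
    c(median = m[["median"]], q1 = m[["q1"]], q3 = m[["q3"]])
  }
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "<cohort_spec> ", x$n_control, " controls (",
    x$control_sex[["F"]], "F/", x$control_sex[["M"]], "M), ",
    x$n_patient, " patients (",
    x$patient_sex[["F"]], "F/", x$patient_sex[["M"]], "M), 2 visits\n",
    sep = ""
  )
  cat(
    " ", length(x$variables), "generated variables;",
    nrow(x$correlation_targets), "correlation targets; pairing",
    x$pairing, "\n"
  )
  invisible(x)
}

normal3 <- function(name, c_m, c_s, b_m, b_s, m_m, m_s) {
  variable_spec(
    name, "normal",
    control = list(mean = c_m, sd = c_s),
    baseline = list(mean = b_m, sd = b_s),
    month6 = list(mean = m_m, sd = m_s)
  )
}

lognormal3_mean_sd <- function(name, c_m, c_s, b_m, b_s, m_m, m_s) {
  variable_spec(
    name, "lognormal",
    control = list(mean = c_m, sd = c_s),
    baseline = list(mean = b_m, sd = b_s),
    month6 = list(mean = m_m, sd = m_s)
  )
}

#' Default cohort specification of the emulated study
#'
#' Encodes the study conditions the generator emulates: 20 obese
#' non-diabetic controls (11F/9M) and 40 obese newly diagnosed T2DM
#' patients (24F/16M) measured at baseline and after six months of
#' metformin monotherapy. Near-symmetric variables carry the printed
#' mean +/- SD per stratum; clearly right-skewed positive variables
#' (triglycerides, urinary creatinine and albumin, insulin and the
#' calculator-style HOMA columns) are moment-matched log-normals so the
#' printed means and SDs are still reproduced without truncation bias; the
#' three plasma adipokines are log-normal from their printed medians and
#' interquartile ranges, with a sex-specific marginal for adropin in
#' controls. Correlation targets are the statistically significant Spearman
#' cells of the study's correlation tables (targets naming a derived index
#' are attached to its monotone raw driver); background physiological
#' correlations are fixed structural values.
#'
#' @return A [cohort_spec()] object.
#' @export
default_spec <- function() {
  variables <- list(
    normal3("age", 56.05, 4.99, 59.28, 7.29, 59.88, 7.29),
    normal3("bmi", 29.59, 6.22, 32.76, 4.83, 32.13, 5.06),
    normal3("whr", 0.95, 0.07, 0.98, 0.06, 0.97, 0.06),
    normal3("glucose", 90.50, 5.09, 113.94, 12.06, 114.22, 14.38),
    normal3("hba1c", 5.21, 0.39, 6.26, 0.61, 6.33, 0.79),
    lognormal3_mean_sd("tg", 162.07, 50.01, 176.84, 93.14, 142.42, 66.25),
    normal3("tc", 181.23, 27.27, 196.66, 44.87, 182.29, 29.10),
    normal3("hdl", 46.80, 8.53, 50.10, 14.77, 51.59, 14.55),
    normal3("ldl", 115.78, 28.44, 113.79, 35.54, 99.21, 27.17),
    normal3("scr", 0.85, 0.10, 0.79, 0.13, 0.85, 0.17),
    lognormal3_mean_sd("ucr", 110.60, 65.43, 100.74, 56.90, 105.51, 52.54),
    lognormal3_mean_sd("ualb", 4.66, 3.81, 5.99, 5.32, 6.05, 5.65),
    lognormal3_mean_sd("insulin", 13.15, 9.72, 10.53, 6.43, 9.52, 5.12),
    lognormal3_mean_sd("homa_ir", 1.16, 0.73, 1.46, 0.83, 1.29, 0.68),
    lognormal3_mean_sd("homa_b", 135.59, 58.60, 78.16, 37.88, 69.06, 32.86),
    normal3("sbp", 122.50, 6.98, 135.69, 10.71, 131.67, 10.95),
    normal3("dbp", 81.25, 3.41, 81.67, 5.07, 78.06, 7.39),
    variable_spec(
      "adropin", "lognormal",
      control = list(
        F = list(median = 0.56, q1 = 0.40, q3 = 0.70),
        M = list(median = 0.79, q1 = 0.71, q3 = 1.13)
      ),
      baseline = list(median = 0.86, q1 = 0.61, q3 = 1.07),
      month6 = list(median = 0.74, q1 = 0.52, q3 = 0.93)
    ),
    variable_spec(
      "irisin", "lognormal",
      control = list(median = 4.99, q1 = 3.29, q3 = 6.16),
      baseline = list(median = 8.83, q1 = 5.63, q3 = 12.39),
      month6 = list(median = 15.28, q1 = 11.39, q3 = 19.78)
    ),
    variable_spec(
      "vaspin", "lognormal",
      control = list(median = 0.35, q1 = 0.21, q3 = 0.99),
      baseline = list(median = 0.12, q1 = 0.07, q3 = 0.29),
      month6 = list(median = 0.29, q1 = 0.17, q3 = 0.66)
    )
  )

  # Significant pre-treatment and post-treatment Spearman cells. Targets
  # printed against a derived index are carried by its monotone raw driver:
  # eGFR falls with serum creatinine and QUICKI falls with insulin, so
  # those targets flip sign onto scr / insulin. HOMA %S is emitted as the
  # exact reciprocal of HOMA-IR, which realises its negative cell
  # automatically, and the weight cell is carried by BMI (weight is
  # BMI x height^2 with height independent of the copula).
  targets <- cor_targets(
    list("vaspin", "insulin", "baseline", 0.491),
    list("vaspin", "homa_ir", "baseline", 0.437),
    list("vaspin", "homa_b", "baseline", 0.352),
    list("irisin", "hba1c", "baseline", -0.430),
    list("irisin", "scr", "baseline", 0.304),
    list("adropin", "tg", "baseline", 0.479),
    list("vaspin", "bmi", "month6", 0.435),
    list("irisin", "insulin", "month6", -0.349),
    list("vaspin", "insulin", "month6", 0.372),
    # printed post-treatment cells below the significance level, retained
    # at their printed values so the month-6 block stays jointly feasible
    # with the strong insulin/HOMA-IR structural link
    list("vaspin", "homa_ir", "month6", 0.349),
    list("irisin", "homa_ir", "month6", -0.087)
  )

  structural <- cor_targets(
    list("insulin", "homa_ir", "all", 0.85),
    list("insulin", "homa_b", "all", 0.60),
    list("homa_ir", "homa_b", "all", 0.45),
    list("glucose", "homa_ir", "all", 0.35),
    list("glucose", "insulin", "all", 0.25),
    list("glucose", "hba1c", "all", 0.50),
    list("tc", "ldl", "all", 0.85),
    list("tc", "hdl", "all", 0.20),
    list("tc", "tg", "all", 0.30),
    list("ldl", "tg", "all", 0.15),
    list("ldl", "hdl", "all", 0.05),
    list("tg", "hdl", "all", -0.35),
    list("sbp", "dbp", "all", 0.60),
    list("bmi", "whr", "all", 0.40)
  )

  cohort_spec(
    variables = variables,
    correlation_targets = targets,
    structural = structural
  )
}
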