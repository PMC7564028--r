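# Descriptive and gated inferential statistics: group summaries,
# percent change following therapy, normality/variance gating into the
# appropriate two-group or paired test, and Spearman correlation tables.

#' Percent change following therapy
#'
#' `100 * (after - before) / before`, presentation-rounded to two decimals
#' to match tabular reporting. Works on group-level summary cells (the
#' table convention) and on per-patient values alike.
#'
#' @param before,after Values before and after treatment; `before` must be
#'   non-zero.
#' @param digits Rounding for presentation (default 2; `Inf` disables).
#' @return Percent change.
#' @examples
#' percent_change(113.79, 99.21) # -12.81
#' @export
percent_change <- function(before, after, digits = 2) {
  if (any(!is.na(before) & before == 0)) {
    stop("percent change undefined for before = 0", call. = FALSE)
  }
  pc <- 100 * (after - before) / before
  if (is.finite(digits)) round(pc, digits) else pc
}

#' Summarise a variable as mean +/- SD or median (IQR)
#'
#' @param values Numeric vector (n >= 2 after NA removal).
#' @param style `"mean_sd"` or `"median_iqr"`.
#' @return One-row tibble: `n` plus `mean`/`sd` or `median`/`q1`/`q3`.
#' @export
summarize_values <- function(values, style = c("mean_sd", "median_iqr")) {
  style <- match.arg(style)
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (style == "mean_sd") {
    tibble::tibble(
      n = length(values),
      mean = mean(values),
      sd = stats::sd(values)
    )
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
  }
}

shapiro_p <- function(x) {
  # Shapiro-Wilk is defined for 3..5000 observations with non-zero range
  if (length(x) > 5000) x <- x[seq_len(5000)]
  if (length(x) < 3 || diff(range(x)) == 0) {
    return(NA_real_)
  }
  stats::shapiro.test(x)$p.value
}

comparison_row <- function(variable, design, test_used, statistic, p_value,
                           shapiro_p_x, shapiro_p_y, levene_p, alpha) {
  tibble::tibble(
    variable = variable,
    design = design,
    test_used = test_used,
    statistic = unname(statistic),
    p_value = p_value,
    significant = !is.na(p_value) & p_value < alpha,
    shapiro_p_x = shapiro_p_x,
    shapiro_p_y = shapiro_p_y,
    levene_p = levene_p
  )
}

#' Gated two-group comparison (independent samples)
#'
#' Reproduces the conventional clinical-statistics gate: Shapiro-Wilk
#' normality in each group and Levene homogeneity of variance at the
#' gating level (default 0.05). If both groups pass normality and the
#' variances are homogeneous, a pooled-variance Student t test is used;
#' otherwise a Mann-Whitney U test (exact for small samples without ties,
#' normal approximation with continuity correction otherwise, the
#' `stats::wilcox.test()` convention).
#'
#' @param x,y Numeric samples (each n >= 3 after NA removal).
#' @param variable Label carried into the result.
#' @param alpha Significance level for the reported test (default 0.05).
#' @param gate_alpha Level of the Shapiro-Wilk/Levene gate (default 0.05).
#' @return One-row tibble: variable, design, test_used, statistic, p_value,
#'   significant, and the gating p-values.
#' @export
compare_independent <- function(x, y, variable = "x", alpha = 0.05,
                                gate_alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  sw_x <- shapiro_p(x)
  sw_y <- shapiro_p(y)
  lev <- levene_p(x, y)
  normal_ok <- !is.na(sw_x) && !is.na(sw_y) &&
    sw_x >= gate_alpha && sw_y >= gate_alpha
  var_ok <- !is.na(lev) && lev >= gate_alpha
  if (normal_ok && var_ok) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    comparison_row(
      variable, "independent", "student_t",
      ht$statistic, ht$p.value, sw_x, sw_y, lev, alpha
    )
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    comparison_row(
      variable, "independent", "mann_whitney",
      ht$statistic, ht$p.value, sw_x, sw_y, lev, alpha
    )
  }
}

levene_p <- function(x, y) {
  values <- c(x, y)
  grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  out <- tryCatch(
    car::leveneTest(values, grp, center = stats::median),
    error = function(e) NULL
  )
  if (is.null(out)) NA_real_ else out[["Pr(>F)"]][1]
}

#' Gated paired comparison (pre vs post)
#'
#' Gates on Shapiro-Wilk normality of the paired differences: a paired t
#' test when the differences look normal, a Wilcoxon signed-rank test
#' otherwise. Zero-variance differences are a degenerate design and raise
#' an error.
#'
#' @param pre,post Equal-length paired vectors (n >= 3 complete pairs).
#' @inheritParams compare_independent
#' @return One-row tibble as in [compare_independent()].
#' @export
compare_paired <- function(pre, post, variable = "x", alpha = 0.05,
                           gate_alpha = 0.05) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]
  post <- post[keep]
  if (length(pre) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0 && all(d == 0)) {
    stop("degenerate paired design: all differences are zero", call. = FALSE)
  }
  sw_d <- shapiro_p(d)
  if (!is.na(sw_d) && sw_d >= gate_alpha) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    comparison_row(
      variable, "paired", "paired_t",
      ht$statistic, ht$p.value, sw_d, NA_real_, NA_real_, alpha
    )
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE, correct = TRUE))
    comparison_row(
      variable, "paired", "wilcoxon",
      ht$statistic, ht$p.value, sw_d, NA_real_, NA_real_, alpha
    )
  }
}

#' Filter a cohort to a named stratum
#'
#' Strata are `"control"`, `"t2dm-baseline"` and `"t2dm-month6"`.
#'
#' @param cohort Cohort tibble.
#' @param stratum Stratum name.
#' @return The filtered tibble.
#' @export
filter_stratum <- function(cohort, stratum) {
  switch(stratum,
    "control" = dplyr::filter(cohort, .data$group == "control"),
    "t2dm-baseline" = dplyr::filter(
      cohort, .data$group == "t2dm", .data$visit == "baseline"
    ),
    "t2dm-month6" = dplyr::filter(
      cohort, .data$group == "t2dm", .data$visit == "month6"
    ),
    stop("unknown stratum: ", stratum, call. = FALSE)
  )
}

#' Spearman correlation table
#'
#' Spearman rank correlation with p-value for every (row, column) variable
#' pair on complete cases within one stratum, flagging non-significant
#' cells and cells with insufficient data.
#'
#' @param cohort Cohort tibble (already containing every named variable).
#' @param row_vars,col_vars Character vectors of variable names.
#' @param stratum Stratum passed to [filter_stratum()], or `NULL` to use
#'   the cohort as given.
#' @param alpha Significance flag level (default 0.05).
#' @return Tibble: var_a, var_b, stratum, rho, p_value, n, significant,
#'   note ("insufficient n" when fewer than 3 complete cases).
#' @export
correlation_table <- function(cohort, row_vars, col_vars, stratum = NULL,
                              alpha = 0.05) {
  data <- if (is.null(stratum)) cohort else filter_stratum(cohort, stratum)
  if (nrow(data) == 0) stop("empty stratum", call. = FALSE)
  grid <- expand.grid(
    var_a = row_vars, var_b = col_vars,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- data[[grid$var_a[i]]]
    b <- data[[grid$var_b[i]]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(
        var_a = grid$var_a[i], var_b = grid$var_b[i],
        stratum = stratum %||% "given", rho = NA_real_, p_value = NA_real_,
        n = n, significant = NA, note = "insufficient n"
      ))
    }
    ct <- suppressWarnings(
      stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(
      var_a = grid$var_a[i], var_b = grid$var_b[i],
      stratum = stratum %||% "given",
      rho = unname(ct$estimate), p_value = ct$p.value, n = n,
      significant = ct$p.value < alpha, note = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-patient percent-change correlations
#'
#' Computes the within-patient percent change from baseline to month 6 for
#' each requested variable, then Spearman-correlates adipokine percent
#' changes with metabolic-parameter percent changes. Patients lacking
#' either visit are excluded.
#'
#' @param cohort Cohort tibble with both patient visits.
#' @param adipokines Variables whose percent change forms the rows
#'   (default the three plasma adipokines).
#' @param params Variables whose percent change forms the columns.
#' @param alpha Significance flag level.
#' @return Tibble as in [correlation_table()], on the percent-change scale.
#' @export
delta_correlations <- function(cohort,
                               adipokines = c("adropin", "irisin", "vaspin"),
                               params = c("homa_ir", "homa_b", "homa_s"),
                               alpha = 0.05) {
  vars <- unique(c(adipokines, params))
  pat <- dplyr::filter(cohort, .data$group == "t2dm")
  base <- dplyr::filter(pat, .data$visit == "baseline")
  m6 <- dplyr::filter(pat, .data$visit == "month6")
  common <- intersect(base$subject_id, m6$subject_id)
  if (length(common) < 3) {
    stop("need at least 3 patients with both visits", call. = FALSE)
  }
  base <- base[match(common, base$subject_id), ]
  m6 <- m6[match(common, m6$subject_id), ]
  deltas <- tibble::as_tibble(lapply(
    stats::setNames(vars, vars),
    function(v) percent_change(base[[v]], m6[[v]], digits = Inf)
  ))
  correlation_table(deltas, adipokines, setdiff(params, adipokines),
    stratum = NULL, alpha = alpha
  )
}
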