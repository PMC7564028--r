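# Gaussian-copula cohort simulation. Per stratum a latent standard-normal
# vector with the target rank-correlation structure is drawn per subject
# and pushed through each variable's marginal; the month-6 visit of a
# patient is a correlated redraw of the baseline latent vector, so paired
# structure and per-visit treatment effects coexist.

# Latent Pearson correlation matrix for one stratum, from the Spearman
# targets plus the structural background. Repaired to the nearest positive
# definite correlation matrix (with a warning) if the requested cells are
# jointly infeasible.
latent_correlation <- function(spec, stratum) {
  vn <- names(spec$variables)
  p <- length(vn)
  C <- diag(p)
  dimnames(C) <- list(vn, vn)
  fill <- function(tab) {
    for (i in seq_len(nrow(tab))) {
      a <- tab$var_a[i]
      b <- tab$var_b[i]
      C[a, b] <<- C[b, a] <<- spearman_to_pearson(tab$rho[i])
    }
  }
  fill(spec$structural)
  fill(spec$correlation_targets[spec$correlation_targets$stratum == stratum, ])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("target correlation matrix for stratum '", stratum,
      "' is not positive definite; repaired with Matrix::nearPD",
      call. = FALSE
    )
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    dimnames(C) <- list(vn, vn)
  }
  C
}

# z: latent standard normal draws for one variable; returns values on the
# data scale. Normal-family draws falling at or below zero are redrawn from
# the positive tail (physiological floor), which is a negligible-mass event
# for every default normal variable.
transform_marginal <- function(z, m) {
  if (m$family == "normal") {
    x <- m$mean + m$sd * z
    bad <- which(x <= 0)
    if (length(bad)) {
      lo <- stats::pnorm(-m$mean / m$sd)
      x[bad] <- m$mean + m$sd * stats::qnorm(stats::runif(length(bad), lo, 1))
    }
    x
  } else {
    stats::qlnorm(stats::pnorm(z), meanlog = m$meanlog, sdlog = m$sdlog)
  }
}

# Apply marginals of one stratum to a latent matrix Z (n x p), honouring
# sex-specific marginals where declared.
apply_marginals <- function(Z, spec, stratum, sex) {
  out <- Z
  for (j in seq_along(spec$variables)) {
    vs <- spec$variables[[j]]
    m <- vs$strata[[stratum]]
    if (!is.null(m$family)) {
      out[, j] <- transform_marginal(Z[, j], m)
    } else {
      for (s in c("F", "M")) {
        idx <- which(sex == s)
        if (length(idx)) out[idx, j] <- transform_marginal(Z[idx, j], m[[s]])
      }
    }
  }
  out
}

draw_latent <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% L
}

#' Simulate a synthetic cohort
#'
#' Draws a full long-format cohort from a [cohort_spec()]: one baseline row
#' per control subject and a baseline plus month-6 row per patient. Latent
#' Gaussian-copula draws realise the stratum-specific Spearman correlation
#' targets; a patient's month-6 latent vector mixes the baseline vector
#' with fresh noise so that the same-variable across-visit Spearman
#' correlation equals the spec's `pairing` value. Sex counts are fixed (not
#' sampled), hypertension is a per-subject Bernoulli flag constant across
#' visits, height is constant per subject, weight is BMI x height^2, age
#' advances deterministically between visits, and the calculator-style
#' `homa_s` column is emitted as 100 / `homa_ir`.
#'
#' @param spec A [cohort_spec()]; defaults to [default_spec()].
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return A tibble of subject-visit rows (see [cohort_schema()]).
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(cohort) # 20 + 40 + 40
#' @export
simulate_cohort <- function(spec = default_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  vn <- names(spec$variables)

  ctrl_sex <- rep(c("F", "M"), times = c(spec$control_sex[["F"]], spec$control_sex[["M"]]))
  pat_sex <- rep(c("F", "M"), times = c(spec$patient_sex[["F"]], spec$patient_sex[["M"]]))
  nc <- spec$n_control
  np <- spec$n_patient

  ctrl_height <- transform_marginal(
    stats::rnorm(nc),
    list(family = "normal", mean = spec$height[["mean"]], sd = spec$height[["sd"]])
  )
  pat_height <- transform_marginal(
    stats::rnorm(np),
    list(family = "normal", mean = spec$height[["mean"]], sd = spec$height[["sd"]])
  )
  ctrl_htn <- stats::rbinom(nc, 1, spec$htn_prev[["control"]])
  pat_htn <- stats::rbinom(np, 1, spec$htn_prev[["t2dm"]])

  Rc <- latent_correlation(spec, "control")
  Rb <- latent_correlation(spec, "baseline")
  Rm <- latent_correlation(spec, "month6")

  Zc <- draw_latent(nc, Rc)
  Zb <- draw_latent(np, Rb)
  a <- spearman_to_pearson(spec$pairing)
  Zm <- a * Zb + sqrt(1 - a^2) * draw_latent(np, Rm)

  Xc <- apply_marginals(Zc, spec, "control", ctrl_sex)
  Xb <- apply_marginals(Zb, spec, "baseline", pat_sex)
  Xm <- apply_marginals(Zm, spec, "month6", pat_sex)
  colnames(Xc) <- colnames(Xb) <- colnames(Xm) <- vn

  assemble <- function(X, ids, group, visit, sex, height, htn, age_shift = 0) {
    d <- tibble::as_tibble(X)
    g <- function(nm) if (nm %in% vn) d[[nm]] else rep(NA_real_, nrow(d))
    out <- tibble::tibble(
      subject_id = ids,
      group = group,
      visit = visit,
      sex = sex,
      age = g("age") + age_shift,
      weight = g("bmi") * height^2,
      height = height,
      whr = g("whr"),
      hypertension = htn,
      glucose = g("glucose"),
      insulin = g("insulin"),
      hba1c = g("hba1c"),
      tc = g("tc"),
      hdl = g("hdl"),
      ldl = g("ldl"),
      tg = g("tg"),
      scr = g("scr"),
      ucr = g("ucr"),
      ualb = g("ualb"),
      black = 0L,
      sbp = g("sbp"),
      dbp = g("dbp"),
      adropin = g("adropin"),
      irisin = g("irisin"),
      vaspin = g("vaspin"),
      homa_ir = g("homa_ir"),
      homa_b = g("homa_b"),
      homa_s = 100 / g("homa_ir")
    )
    # any further generated variables ride along as extra columns
    extra <- setdiff(vn, c(names(out), "bmi"))
    for (v in extra) out[[v]] <- d[[v]]
    out
  }

  ctrl_ids <- sprintf("C%02d", seq_len(nc))
  pat_ids <- sprintf("P%02d", seq_len(np))
  base_m6 <- dplyr::bind_rows(
    assemble(Xb, pat_ids, "t2dm", "baseline", pat_sex, pat_height, pat_htn),
    assemble(Xm, pat_ids, "t2dm", "month6", pat_sex, pat_height, pat_htn,
      age_shift = NA
    )
  )
  # month-6 age is the baseline draw advanced by the visit interval, not an
  # independent redraw
  m6 <- base_m6$visit == "month6"
  base_m6$age[m6] <- base_m6$age[!m6] + spec$age_drift

  dplyr::bind_rows(
    assemble(Xc, ctrl_ids, "control", "baseline", ctrl_sex, ctrl_height, ctrl_htn),
    base_m6
  )
}

#' Cohort table schema
#'
#' Required and optional columns of the long-format subject-visit cohort
#' table. The calculator-style HOMA columns (`homa_ir`, `homa_b`, `homa_s`)
#' are optional primary data: they cannot be recomputed from the raw fields
#' (the study derived them from a closed physiological model), so the
#' generator emits them directly and downstream stages treat them as
#' measurements.
#'
#' @return A list with `required` and `optional` column-name vectors.
#' @export
cohort_schema <- function() {
  list(
    required = c(
      "subject_id", "group", "visit", "sex", "age", "weight", "height",
      "whr", "hypertension", "glucose", "insulin", "hba1c", "tc", "hdl",
      "ldl", "tg", "scr", "ucr", "ualb", "black", "sbp", "dbp",
      "adropin", "irisin", "vaspin"
    ),
    optional = c("homa_ir", "homa_b", "homa_s")
  )
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, factor-level validity, positivity of
#' concentrations and anthropometrics, the 0/1 hypertension flag, that
#' month-6 rows occur only in the t2dm group, and uniqueness of
#' (subject_id, visit).
#'
#' @param cohort A data frame to validate.
#' @param allow_extra Allow columns beyond the schema (default FALSE).
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, allow_extra = FALSE) {
  sch <- cohort_schema()
  miss <- setdiff(sch$required, names(cohort))
  if (length(miss)) {
    stop("missing cohort columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(cohort), c(sch$required, sch$optional))
  if (length(extra) && !allow_extra) {
    stop("unknown cohort columns: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!all(cohort$group %in% c("control", "t2dm"))) {
    stop("group must be 'control' or 't2dm'", call. = FALSE)
  }
  if (!all(cohort$visit %in% c("baseline", "month6"))) {
    stop("visit must be 'baseline' or 'month6'", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("F", "M"))) stop("sex must be F or M", call. = FALSE)
  if (any(cohort$visit == "month6" & cohort$group != "t2dm")) {
    stop("visit 'month6' is only valid for group 't2dm'", call. = FALSE)
  }
  htn <- cohort$hypertension
  if (any(!is.na(htn) & !htn %in% c(0, 1))) {
    stop("hypertension must be 0/1", call. = FALSE)
  }
  if (anyDuplicated(cohort[, c("subject_id", "visit")])) {
    stop("(subject_id, visit) pairs must be unique", call. = FALSE)
  }
  pos_cols <- c(
    "age", "weight", "height", "whr", "glucose", "insulin", "hba1c",
    "tc", "hdl", "ldl", "tg", "scr", "ucr", "sbp", "dbp",
    "adropin", "irisin", "vaspin"
  )
  for (cl in pos_cols) {
    v <- cohort[[cl]]
    if (any(!is.na(v) & v <= 0)) {
      stop("column ", cl, " must be strictly positive", call. = FALSE)
    }
  }
  if (any(!is.na(cohort$ualb) & cohort$ualb < 0)) {
    stop("ualb must be non-negative", call. = FALSE)
  }
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' RFC-4180 CSV with a header row, '.' decimal separator and empty cells
#' for missing values; the table is validated against [cohort_schema()] on
#' both paths.
#'
#' @param path File path.
#' @param allow_extra Allow columns beyond the schema.
#' @return `read_cohort()` returns a validated tibble.
#' @export
read_cohort <- function(path, allow_extra = FALSE) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort, allow_extra = allow_extra)
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, allow_extra = TRUE)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
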