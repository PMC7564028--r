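# Derived clinical indices used throughout the panel-discovery pipeline.
# All functions are vectorised, pure, and enforce strict unit contracts:
# insulin in uU/mL (= mIU/L), glucose in mg/dL, creatinine in mg/dL,
# urinary albumin in ug/mL, WHR dimensionless, HbA1c in %.

#' Body mass index
#'
#' @param weight Body weight in kg.
#' @param height Body height in m.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(81, 1.8)
#' @export
bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / height^2
}

#' HOMA1 insulin-resistance index
#'
#' Classical single-equation homeostasis-model assessment of insulin
#' resistance: fasting insulin (uU/mL) times fasting glucose (mg/dL)
#' divided by 405.
#'
#' @param insulin Fasting insulin, uU/mL.
#' @param glucose Fasting plasma glucose, mg/dL.
#' @return Dimensionless HOMA1-IR.
#' @examples
#' homa1_ir(4.05, 100) # 1
#' @export
homa1_ir <- function(insulin, glucose) {
  check_positive(insulin, "insulin")
  check_positive(glucose, "glucose")
  insulin * glucose / 405
}

#' HOMA1 beta-cell function (%B)
#'
#' Classical surrogate for beta-cell secretory function:
#' 360 * insulin / (glucose - 63). Undefined at glucose <= 63 mg/dL.
#'
#' @inheritParams homa1_ir
#' @return Percent beta-cell function.
#' @export
homa1_percent_b <- function(insulin, glucose) {
  check_positive(insulin, "insulin")
  if (any(!is.na(glucose) & glucose <= 63)) {
    stop("undefined %B: glucose <= 63 mg/dL", call. = FALSE)
  }
  360 * insulin / (glucose - 63)
}

#' HOMA1 insulin sensitivity (%S)
#'
#' Reciprocal convention: %S = 100 / HOMA-IR.
#'
#' @param homa_ir Dimensionless HOMA-IR value.
#' @return Percent insulin sensitivity.
#' @export
homa1_percent_s <- function(homa_ir) {
  check_positive(homa_ir, "homa_ir")
  100 / homa_ir
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' QUICKI = 1 / (log10 insulin + log10 glucose), with insulin in uU/mL and
#' glucose in mg/dL. The logarithm base is configurable but defaults to 10,
#' the base of the original index definition.
#'
#' @inheritParams homa1_ir
#' @param base Logarithm base (default 10).
#' @return Dimensionless QUICKI.
#' @export
quicki <- function(insulin, glucose, base = 10) {
  check_positive(insulin, "insulin")
  check_positive(glucose, "glucose")
  s <- log(insulin, base = base) + log(glucose, base = base)
  if (any(!is.na(s) & s == 0)) {
    stop("QUICKI undefined: log(insulin) + log(glucose) is zero", call. = FALSE)
  }
  1 / s
}

#' Estimated glucose disposal rate (eGDR)
#'
#' Linear clamp-calibrated surrogate of whole-body insulin sensitivity:
#' eGDR (mg/kg/min) = 24.31 - 12.22 WHR - 3.29 hypertension - 0.57 HbA1c.
#' The raw formula value is returned without clipping; values below
#' 7.5 mg/kg/min indicate reduced tissue sensitivity to insulin (see
#' [ir_flag()]).
#'
#' @param whr Waist-to-hip ratio (dimensionless).
#' @param hypertension Hypertension status, 0 or 1.
#' @param hba1c Glycated haemoglobin, %.
#' @return eGDR in mg/kg/min (may be negative).
#' @export
egdr <- function(whr, hypertension, hba1c) {
  check_positive(whr, "whr")
  check_positive(hba1c, "hba1c")
  if (any(!is.na(hypertension) & !hypertension %in% c(0, 1))) {
    stop("hypertension must be 0 or 1", call. = FALSE)
  }
  24.31 - 12.22 * whr - 3.29 * hypertension - 0.57 * hba1c
}

#' Reduced-insulin-sensitivity flag
#'
#' TRUE when eGDR is strictly below 7.5 mg/kg/min, the conventional
#' threshold for reduced tissue sensitivity to insulin.
#'
#' @param egdr eGDR values in mg/kg/min.
#' @param threshold Decision threshold (default 7.5 mg/kg/min).
#' @return Logical vector.
#' @export
ir_flag <- function(egdr, threshold = 7.5) {
  egdr < threshold
}

#' Estimated GFR by the four-variable MDRD equation
#'
#' eGFR = 175 * sCr^-1.154 * age^-0.203 * 1.212 (if black) * 0.742
#' (if female), in mL/min per 1.73 m^2.
#'
#' @param scr Serum creatinine, mg/dL.
#' @param age Age in years.
#' @param sex "F" or "M".
#' @param black Race indicator 0/1 for the MDRD coefficient.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_mdrd <- function(scr, age, sex, black = 0) {
  check_positive(scr, "scr")
  check_positive(age, "age")
  sex <- as.character(sex)
  if (any(!is.na(sex) & !sex %in% c("F", "M"))) {
    stop("sex must be \"F\" or \"M\"", call. = FALSE)
  }
  out <- 175 * scr^-1.154 * age^-0.203
  out <- out * ifelse(!is.na(black) & black == 1, 1.212, 1)
  out * ifelse(!is.na(sex) & sex == "F", 0.742, 1)
}

#' Urinary albumin-to-creatinine ratio
#'
#' Albumin in ug/mL over creatinine in mg/dL; creatinine is converted to
#' mg/mL (divide by 100) so the ratio comes out in ug albumin per mg
#' creatinine.
#'
#' @param ualb Urinary albumin, ug/mL.
#' @param ucr Urinary creatinine, mg/dL.
#' @return ACR in ug/mg.
#' @export
acr <- function(ualb, ucr) {
  if (any(!is.na(ualb) & ualb < 0)) {
    stop("ualb must be non-negative", call. = FALSE)
  }
  check_positive(ucr, "ucr")
  ualb * 100 / ucr
}

#' Triglyceride-to-HDL ratio
#'
#' Indirect surrogate marker of insulin resistance; both inputs in mg/dL.
#'
#' @param tg Triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @return Dimensionless TG/HDL ratio.
#' @export
tg_hdl <- function(tg, hdl) {
  check_positive(tg, "tg")
  check_positive(hdl, "hdl")
  tg / hdl
}

check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) {
    stop(sprintf("%s must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

# One index definition per row: output column, required raw fields, and a
# guard returning a reason string (or NULL) before the formula is applied.
index_definitions <- function() {
  list(
    bmi = list(
      needs = c("weight", "height"),
      fun = function(r) bmi(r$weight, r$height)
    ),
    homa1_ir = list(
      needs = c("insulin", "glucose"),
      fun = function(r) homa1_ir(r$insulin, r$glucose)
    ),
    homa1_b = list(
      needs = c("insulin", "glucose"),
      guard = function(r) if (r$glucose <= 63) "glucose <= 63",
      fun = function(r) homa1_percent_b(r$insulin, r$glucose)
    ),
    homa1_s = list(
      needs = c("insulin", "glucose"),
      fun = function(r) homa1_percent_s(homa1_ir(r$insulin, r$glucose))
    ),
    quicki = list(
      needs = c("insulin", "glucose"),
      guard = function(r) {
        if (log10(r$insulin) + log10(r$glucose) == 0) "log-sum zero"
      },
      fun = function(r) quicki(r$insulin, r$glucose)
    ),
    egdr = list(
      needs = c("whr", "hypertension", "hba1c"),
      fun = function(r) egdr(r$whr, r$hypertension, r$hba1c)
    ),
    egfr = list(
      needs = c("scr", "age", "sex"),
      fun = function(r) {
        egfr_mdrd(r$scr, r$age, r$sex, if (is.null(r$black) || is.na(r$black)) 0 else r$black)
      }
    ),
    acr = list(
      needs = c("ualb", "ucr"),
      fun = function(r) acr(r$ualb, r$ucr)
    ),
    tg_hdl = list(
      needs = c("tg", "hdl"),
      fun = function(r) tg_hdl(r$tg, r$hdl)
    )
  )
}

#' Compute the full index set for one subject-visit
#'
#' Applies every index formula to a single subject-visit record. Missing
#' raw fields propagate to missing indices with a reason code; an index
#' failure never aborts the batch.
#'
#' Note on HOMA naming: the formula-based columns are `homa1_ir`, `homa1_b`
#' and `homa1_s` (classical single-equation HOMA). Cohorts may additionally
#' carry calculator-style `homa_ir`/`homa_b`/`homa_s` columns as primary
#' data; the two families are deliberately kept under distinct names and
#' never conflated.
#'
#' @param visit A one-row data frame or named list with subject-visit raw
#'   fields (see [cohort_schema()]).
#' @return A list with elements `values` (named numeric/logical vector of
#'   bmi, homa1_ir, homa1_b, homa1_s, quicki, egdr, egfr, acr, tg_hdl,
#'   ir_flag) and `reasons` (named character vector of reason codes for
#'   missing indices).
#' @export
compute_index_set <- function(visit) {
  r <- as.list(visit)
  defs <- index_definitions()
  values <- stats::setNames(rep(NA_real_, length(defs)), names(defs))
  reasons <- character(0)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    missing_fields <- d$needs[vapply(
      d$needs,
      function(f) is.null(r[[f]]) || is.na(r[[f]]),
      logical(1)
    )]
    if (length(missing_fields)) {
      reasons[nm] <- paste("missing:", paste(missing_fields, collapse = ", "))
      next
    }
    if (!is.null(d$guard)) {
      why <- d$guard(r)
      if (!is.null(why)) {
        reasons[nm] <- why
        next
      }
    }
    values[nm] <- tryCatch(d$fun(r), error = function(e) {
      reasons[nm] <<- conditionMessage(e)
      NA_real_
    })
  }
  values <- as.list(values)
  values$ir_flag <- if (is.na(values$egdr)) NA else ir_flag(values$egdr)
  list(values = values, reasons = reasons)
}

#' Append derived index columns to a cohort table
#'
#' Vectorised batch version of [compute_index_set()]: adds `bmi`,
#' `homa1_ir`, `homa1_b`, `homa1_s`, `quicki`, `egdr`, `egfr`, `acr`,
#' `tg_hdl` and `ir_flag` columns. Per-row failures and missing raw fields
#' yield `NA` in the affected cells; existing columns of the same name are
#' refused (indices are computed once).
#'
#' @param cohort A cohort tibble in subject-visit long format.
#' @return The cohort with index columns appended.
#' @export
add_indices <- function(cohort) {
  new_cols <- c(names(index_definitions()), "ir_flag")
  clash <- intersect(new_cols, names(cohort))
  if (length(clash)) {
    stop("cohort already has index columns: ", paste(clash, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(cohort)
  out <- matrix(NA_real_, n, length(new_cols) - 1,
    dimnames = list(NULL, setdiff(new_cols, "ir_flag"))
  )
  for (i in seq_len(n)) {
    vals <- compute_index_set(cohort[i, ])$values
    out[i, ] <- unlist(vals[colnames(out)])
  }
  res <- dplyr::bind_cols(cohort, tibble::as_tibble(out))
  res$ir_flag <- ifelse(is.na(res$egdr), NA, ir_flag(res$egdr))
  res
}
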