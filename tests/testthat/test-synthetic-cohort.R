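# Synthetic-cohort generator: log-normal parameter conversion, the default
# study specification, structural invariants of the simulated table, and
# rank-correlation behaviour of the copula.

test_that("log-normal parameters from median and IQR are exact", {
  p <- lognormal_from_median_iqr(1, exp(-1), exp(1))
  expect_equal(p[["meanlog"]], 0, tolerance = 1e-12)
  expect_equal(p[["sdlog"]], 1.48260221850560186, tolerance = 1e-9)

  p2 <- lognormal_from_median_iqr(0.12, 0.07, 0.29)
  expect_equal(p2[["meanlog"]], -2.12026353620009106, tolerance = 1e-9)
  expect_equal(p2[["sdlog"]], 1.05367478195031722, tolerance = 1e-9)
  # the implied distribution reproduces the printed quartiles
  expect_equal(qlnorm(0.5, p2[["meanlog"]], p2[["sdlog"]]), 0.12, tolerance = 1e-12)
  # quartiles are matched in the geometric-symmetric sense: the IQR ratio
  # is exact even when the printed quartiles are asymmetric about the median
  expect_equal(
    qlnorm(0.75, p2[["meanlog"]], p2[["sdlog"]]) /
      qlnorm(0.25, p2[["meanlog"]], p2[["sdlog"]]),
    0.29 / 0.07,
    tolerance = 1e-9
  )

  expect_error(lognormal_from_median_iqr(1, 2, 3), "q1 < median")
  expect_error(lognormal_from_median_iqr(1, -1, 3), "q1 < median")
})

test_that("moment-matched log-normal reproduces mean and SD exactly", {
  p <- lognormal_from_mean_sd(10.53, 6.43)
  m <- exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
  v <- (exp(p[["sdlog"]]^2) - 1) * exp(2 * p[["meanlog"]] + p[["sdlog"]]^2)
  expect_equal(m, 10.53, tolerance = 1e-12)
  expect_equal(sqrt(v), 6.43, tolerance = 1e-12)
  expect_error(lognormal_from_mean_sd(-1, 2), "positive")
})

test_that("default spec encodes the study conditions", {
  sp <- default_spec()
  expect_equal(sp$n_control, 20L)
  expect_equal(sp$n_patient, 40L)
  expect_equal(unname(sp$control_sex), c(11L, 9L))
  expect_equal(unname(sp$patient_sex), c(24L, 16L))
  expect_equal(spec_cell(sp, "vaspin", "baseline")[["median"]], 0.12)
  expect_equal(spec_cell(sp, "glucose", "control")[["mean"]], 90.50)
  expect_equal(spec_cell(sp, "glucose", "control")[["sd"]], 5.09)
  tgt <- sp$correlation_targets
  hit <- tgt[tgt$var_a == "vaspin" & tgt$var_b == "insulin" &
    tgt$stratum == "baseline", ]
  expect_equal(hit$rho, 0.491)
  # control adropin is sex-specific with the printed medians
  expect_equal(spec_cell(sp, "adropin", "control", sex = "F")[["median"]], 0.56)
  expect_equal(spec_cell(sp, "adropin", "control", sex = "M")[["median"]], 0.79)
  # every stratum's latent correlation matrix is positive definite as shipped
  for (s in c("control", "baseline", "month6")) {
    expect_silent(C <- adipopanel:::latent_correlation(sp, s))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("simulated cohort has the study's structure and is reproducible", {
  co <- simulate_cohort(default_spec(), seed = 1)
  expect_equal(nrow(co), 100) # 20 controls + 40 patients x 2 visits
  expect_silent(validate_cohort(co))
  expect_equal(sum(co$group == "control"), 20)
  expect_equal(sum(co$group == "t2dm" & co$visit == "baseline"), 40)
  expect_equal(sum(co$group == "t2dm" & co$visit == "month6"), 40)
  ctrl <- co[co$group == "control", ]
  expect_equal(as.integer(table(ctrl$sex)[c("F", "M")]), c(11L, 9L))
  pat <- co[co$group == "t2dm" & co$visit == "baseline", ]
  expect_equal(as.integer(table(pat$sex)[c("F", "M")]), c(24L, 16L))

  # same seed, identical table; different seed, different values
  expect_identical(co, simulate_cohort(default_spec(), seed = 1))
  expect_false(identical(co, simulate_cohort(default_spec(), seed = 2)))

  # subject-level constancy across visits: sex, height, hypertension
  m6 <- co[co$visit == "month6", ]
  b <- co[co$group == "t2dm" & co$visit == "baseline", ]
  m6 <- m6[match(b$subject_id, m6$subject_id), ]
  expect_identical(b$sex, m6$sex)
  expect_identical(b$height, m6$height)
  expect_identical(b$hypertension, m6$hypertension)
  expect_equal(m6$age, b$age + default_spec()$age_drift)
  # calculator-style %S is the exact reciprocal of the HOMA-IR column
  expect_equal(co$homa_s, 100 / co$homa_ir, tolerance = 1e-12)
})

test_that("raising a correlation target raises the realized Spearman rho", {
  mk <- function(rho) {
    sp <- small_spec(n_control = 4, n_patient = 400)
    sp$correlation_targets <- tibble::tibble(
      var_a = "vaspin", var_b = "insulin", stratum = "baseline", rho = rho
    )
    co <- simulate_cohort(sp, seed = 11)
    b <- filter_stratum(co, "t2dm-baseline")
    cor(b$vaspin, b$insulin, method = "spearman")
  }
  lo <- mk(0.2)
  hi <- mk(0.7)
  expect_gt(hi, lo)
  expect_lt(abs(lo - 0.2), 0.15)
  expect_lt(abs(hi - 0.7), 0.15)
})

test_that("within-patient pairing matches the spec value at large n", {
  sp <- small_spec(n_control = 4, n_patient = 1500)
  sp$pairing <- 0.7
  co <- simulate_cohort(sp, seed = 3)
  b <- filter_stratum(co, "t2dm-baseline")
  m6 <- filter_stratum(co, "t2dm-month6")
  m6 <- m6[match(b$subject_id, m6$subject_id), ]
  rho <- cor(b$insulin, m6$insulin, method = "spearman")
  expect_equal(rho, 0.7, tolerance = 0.05)
})

test_that("cohort CSV round-trips and the schema validator gates columns", {
  co <- simulate_cohort(small_spec(), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, allow_extra = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)

  bad <- co
  bad$mystery <- 1
  expect_error(validate_cohort(bad), "unknown cohort columns")
  expect_silent(validate_cohort(bad, allow_extra = TRUE))

  noid <- co[, setdiff(names(co), "subject_id")]
  expect_error(validate_cohort(noid), "missing cohort columns")

  dup <- co
  dup$visit[dup$group == "control"] <- "baseline"
  dup$subject_id[1:2] <- "C01"
  expect_error(validate_cohort(dup), "unique")

  wrongvisit <- co
  wrongvisit$visit[wrongvisit$group == "control"][1] <- "month6"
  expect_error(validate_cohort(wrongvisit), "month6")

  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "no such cohort")
})
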