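# Statistics layer: percent change, summaries, the Shapiro-Wilk/Levene
# test gate, correlation tables and per-patient percent-change coupling.

test_that("percent change reproduces printed therapy-response cells", {
  expect_equal(percent_change(113.79, 99.21), -12.81)
  expect_equal(percent_change(0.12, 0.29), 141.67)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(10, 15, digits = Inf), 50)
  expect_error(percent_change(0, 1), "before = 0")
})

test_that("summaries return mean/SD or median/IQR with sample conventions", {
  ms <- summarize_values(c(1, 2, 3), "mean_sd")
  expect_equal(ms$mean, 2)
  expect_equal(ms$sd, 1) # n-1 denominator
  mi <- summarize_values(c(1, 2, 3, 4), "median_iqr")
  expect_equal(mi$median, 2.5)
  expect_equal(mi$n, 4)
  expect_error(summarize_values(1, "mean_sd"), "at least 2")
})

test_that("independent comparison gates into t or Mann-Whitney correctly", {
  set.seed(7)
  x <- rnorm(60, 10, 2)
  y <- rnorm(60, 11, 2)
  res <- compare_independent(x, y, variable = "demo")
  expect_equal(res$test_used, "student_t")
  expect_equal(res$design, "independent")
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  skewed <- rexp(60)^3
  res2 <- compare_independent(skewed, rnorm(60, 1), variable = "skewed")
  expect_equal(res2$test_used, "mann_whitney")

  # identical samples: no evidence of difference
  z <- rnorm(30)
  res3 <- compare_independent(z, z)
  expect_gt(res3$p_value, 0.95)
  expect_false(res3$significant)

  expect_error(compare_independent(c(1, 2), rnorm(10)), "at least 3")
})

test_that("gating is deterministic: same data, same test choice", {
  set.seed(21)
  x <- rexp(40)
  y <- rnorm(40)
  a <- compare_independent(x, y)
  b <- compare_independent(x, y)
  expect_identical(a, b)
})

test_that("paired comparison gates on differences and flags degeneracy", {
  set.seed(5)
  pre <- rnorm(30, 10)
  post <- pre + 2 + rnorm(30, sd = 0.5)
  res <- compare_paired(pre, post, variable = "shift")
  expect_equal(res$test_used, "paired_t")
  expect_true(res$significant)

  near <- pre + rnorm(30, sd = 1e-3)
  res2 <- compare_paired(pre, near)
  expect_gt(res2$p_value, 0.05)
  expect_false(res2$significant)

  # skewed differences route to the signed-rank test
  res3 <- compare_paired(pre, pre + rexp(30)^3)
  expect_equal(res3$test_used, "wilcoxon")

  expect_error(compare_paired(pre, pre), "degenerate")
  expect_error(compare_paired(pre, post[-1]), "equal length")
})

test_that("empirical level of the gated two-group test is near nominal", {
  # moderately sized null check; the full 1000-rep calibration lives in
  # the acceptance suite
  set.seed(19)
  rejections <- vapply(seq_len(200), function(i) {
    compare_independent(rnorm(20), rnorm(20))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("Spearman tables are monotone-invariant and flag sparse cells", {
  set.seed(13)
  d <- tibble::tibble(
    a = runif(40, 1, 5),
    b = NA_real_,
    c = rnorm(40)
  )
  d$b <- d$a^3 # strictly monotone in a
  tab <- correlation_table(d, "a", c("b", "c"))
  ab <- tab[tab$var_b == "b", ]
  expect_equal(ab$rho, 1)
  # invariance under a strictly monotone transform of either variable
  d2 <- d
  d2$a <- log(d2$a)
  tab2 <- correlation_table(d2, "a", c("b", "c"))
  expect_equal(tab$rho, tab2$rho, tolerance = 1e-12)

  sparse <- tibble::tibble(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2))
  tab3 <- correlation_table(sparse, "a", "b")
  expect_equal(tab3$note, "insufficient n")
  expect_error(correlation_table(d[0, ], "a", "b"), "empty stratum")
})

test_that("large independent samples give small, non-significant rho", {
  set.seed(3)
  d <- tibble::tibble(a = rnorm(400), b = rnorm(400))
  tab <- correlation_table(d, "a", "b")
  expect_lt(abs(tab$rho), 0.12)
  expect_false(tab$significant)
})

test_that("delta correlations couple per-patient percent changes", {
  co <- simulate_cohort(small_spec(n_patient = 40), seed = 17)
  # construct perfect coupling: homa_ir percent change == vaspin's
  b <- co$group == "t2dm" & co$visit == "baseline"
  m <- co$group == "t2dm" & co$visit == "month6"
  pcv <- co$vaspin[m] / co$vaspin[b]
  co$homa_ir[m] <- co$homa_ir[b] * pcv
  co$homa_s <- 100 / co$homa_ir
  dc <- delta_correlations(co, adipokines = "vaspin", params = "homa_ir")
  expect_equal(dc$rho, 1)
  # and the reciprocal column couples with flipped sign
  dc2 <- delta_correlations(co, adipokines = "vaspin", params = "homa_s")
  expect_equal(dc2$rho, -1)

  # shuffled pairing destroys the coupling
  co2 <- co
  co2$homa_ir[m] <- co$homa_ir[b] * sample(pcv)
  dc3 <- delta_correlations(co2, adipokines = "vaspin", params = "homa_ir")
  expect_lt(abs(dc3$rho), 0.5)

  expect_error(
    delta_correlations(co[co$visit == "baseline", ]),
    "both visits"
  )
})
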