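# Mahalanobis discriminant: split arithmetic, decision geometry, ridge
# fallback, the brute-force oracle, and statistical sanity of test ACC.

test_that("stratified split sizes follow round-half-up of 2N/3 per class", {
  labels <- rep(c("a", "b"), c(20, 40))
  sp <- stratified_split(labels, seed = 4)
  expect_equal(unname(sp$counts$a), c(13, 7))
  expect_equal(unname(sp$counts$b), c(27, 13))
  # conservation and disjointness
  expect_setequal(c(sp$learning, sp$test), seq_along(labels))
  expect_length(intersect(sp$learning, sp$test), 0)
  expect_equal(sum(labels[sp$learning] == "a"), 13)

  tiny <- stratified_split(rep(c("a", "b"), each = 3), seed = 1)
  expect_equal(unname(tiny$counts$a), c(2, 1))

  expect_identical(
    stratified_split(labels, seed = 99),
    stratified_split(labels, seed = 99)
  )
  expect_false(identical(
    stratified_split(labels, seed = 1)$learning,
    stratified_split(labels, seed = 2)$learning
  ))
  expect_error(stratified_split(rep(c("a", "b"), c(2, 10))), "fewer than 3")
  expect_error(stratified_split(rep("a", 10)), "2 classes")
})

test_that("subject-level split keeps all rows of a subject on one side", {
  sid <- rep(sprintf("S%02d", 1:30), each = 2)
  labels <- rep(rep(c("ctrl", "case"), c(10, 20)), each = 2)
  sp <- stratified_split(labels, seed = 8, subject_ids = sid)
  learn_subj <- unique(sid[sp$learning])
  test_subj <- unique(sid[sp$test])
  expect_length(intersect(learn_subj, test_subj), 0)
  expect_equal(unname(sp$counts$ctrl), c(7, 3)) # subjects, not rows
  expect_equal(unname(sp$counts$case), c(13, 7))

  mixed <- labels
  mixed[1] <- "case" # subject S01 now spans both classes
  expect_error(
    stratified_split(mixed, seed = 1, subject_ids = sid),
    "same class"
  )
})

test_that("1-D decision boundary sits at the midpoint of the centroids", {
  x <- matrix(c(rnorm(50, 0, 1), rnorm(50, 10, 1)), ncol = 1)
  y <- rep(c("low", "high"), each = 50)
  # force exact means for a sharp geometric check
  x[1:50] <- x[1:50] - mean(x[1:50])
  x[51:100] <- x[51:100] - mean(x[51:100]) + 10
  model <- fit_mahalanobis_lda(x, y)
  expect_equal(classify(model, matrix(4.9)), "low")
  expect_equal(classify(model, matrix(5.1)), "high")
  # exact tie at the midpoint goes to the first class in the model
  expect_equal(classify(model, matrix(5)), model$classes[1])
  # a class centroid is classified as its own class
  expect_equal(classify(model, model$centroids[1, , drop = FALSE]), model$classes[1])
  expect_equal(classify(model, model$centroids[2, , drop = FALSE]), model$classes[2])
})

test_that("duplicated feature engages the ridge without changing calls", {
  set.seed(31)
  x1 <- matrix(c(rnorm(30, 0), rnorm(30, 3)), ncol = 1)
  y <- rep(c("a", "b"), each = 30)
  xdup <- cbind(x1, x1)
  single <- fit_mahalanobis_lda(x1, y)
  doubled <- fit_mahalanobis_lda(xdup, y)
  expect_gt(doubled$ridge, 0)
  expect_equal(single$ridge, 0)
  grid <- matrix(seq(-3, 6, length.out = 40), ncol = 1)
  expect_identical(classify(single, grid), classify(doubled, cbind(grid, grid)))
})

test_that("degenerate fits are rejected with informative errors", {
  y <- rep(c("a", "b"), each = 5)
  x <- cbind(ok = rnorm(10), flat = rep(1, 10))
  expect_error(fit_mahalanobis_lda(x, y), "flat")
  expect_error(fit_mahalanobis_lda(matrix(rnorm(10)), rep("a", 10)), "2 classes")
  expect_error(
    fit_mahalanobis_lda(matrix(c(NA, rnorm(9))), y),
    "complete-case"
  )
  model <- fit_mahalanobis_lda(matrix(rnorm(10)), y)
  expect_error(classify(model, matrix(rnorm(4), 2, 2)), "dimension")
})

test_that("classification is invariant under invertible affine maps", {
  set.seed(12)
  x <- cbind(rnorm(60), rnorm(60, sd = 3))
  x[31:60, ] <- x[31:60, ] + 2
  y <- rep(c("a", "b"), each = 30)
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)
  model <- fit_mahalanobis_lda(x, y, ridge = 0)
  model_t <- fit_mahalanobis_lda(x %*% A, y, ridge = 0)
  newx <- cbind(rnorm(25), rnorm(25, sd = 3))
  expect_identical(classify(model, newx), classify(model_t, newx %*% A))
})

test_that("classify agrees with the naive brute-force oracle on small cases", {
  # spot-check here; the exhaustive grid runs in the acceptance suite
  set.seed(2)
  for (p in 1:2) {
    x_learn <- matrix(rnorm(12 * p), 12, p)
    y_learn <- rep(c("a", "b"), each = 6)
    x_test <- matrix(rnorm(8 * p), 8, p)
    model <- fit_mahalanobis_lda(x_learn, y_learn, ridge = 0)
    expect_identical(
      classify(model, x_test),
      oracle_classify(x_learn, y_learn, x_test)
    )
  }
})

test_that("accuracy implements (TP+TN)/(TP+TN+FP+FN)", {
  truth <- c("d", "d", "d", "h", "h", "h")
  pred <- c("d", "d", "d", "d", "h", "h")
  res <- accuracy(pred, truth, positive_class = "d")
  expect_equal(unname(res$confusion), c(3, 2, 1, 0)) # tp tn fp fn
  expect_equal(res$acc, 5 / 6)
  expect_equal(accuracy(truth, truth, "d")$acc, 1)
  flipped <- ifelse(truth == "d", "h", "d")
  expect_equal(accuracy(flipped, truth, "d")$acc, 0)
  expect_error(accuracy(c("x", "d"), truth[1:2], "d"), "outside")
})

test_that("large-sample error rate approaches the Gaussian limit", {
  # two spherical Gaussians at Mahalanobis distance delta: the Bayes (and
  # Mahalanobis-rule) error is pnorm(-delta / 2)
  set.seed(44)
  delta <- 2
  n <- 4000
  x <- rbind(
    cbind(rnorm(n), rnorm(n)),
    cbind(rnorm(n, delta), rnorm(n))
  )
  y <- rep(c("a", "b"), each = n)
  model <- fit_mahalanobis_lda(x, y)
  xt <- rbind(
    cbind(rnorm(n), rnorm(n)),
    cbind(rnorm(n, delta), rnorm(n))
  )
  err <- mean(classify(model, xt) != y)
  expect_lt(abs(err - pnorm(-delta / 2)), 0.02)
})
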