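# Two-class Mahalanobis-distance discriminant classifier: class centroids
# plus a pooled within-class covariance; a point is assigned to the class
# with the smaller covariance-scaled distance. Equal priors, no feature
# standardisation (the distance is affine invariant by construction).

round_half_up <- function(x) floor(x + 0.5)

#' Stratified 2/3 learning, 1/3 test split
#'
#' Per class, `round(2 n / 3)` units (round half up) go to the learning
#' set and the remainder to the test set. Units are rows unless
#' `subject_ids` is supplied, in which case whole subjects are assigned to
#' one side (preventing subject-level leakage when a subject contributes
#' several rows to the same class).
#'
#' @param labels Class labels, one per row (exactly 2 classes, each with
#'   >= 3 units).
#' @param seed Integer seed making the partition reproducible.
#' @param learning_fraction Fraction in the learning set (default 2/3).
#' @param subject_ids Optional per-row subject identifiers for
#'   subject-level splitting; a subject's rows must share one class.
#' @return List with integer row indices `learning` and `test`, and the
#'   per-class learning/test counts.
#' @export
stratified_split <- function(labels, seed = 1, learning_fraction = 2 / 3,
                             subject_ids = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("exactly 2 classes required", call. = FALSE)
  units <- if (is.null(subject_ids)) {
    data.frame(unit = seq_along(labels), class = labels)
  } else {
    u <- unique(data.frame(unit = as.character(subject_ids), class = labels))
    if (anyDuplicated(u$unit)) {
      stop("a subject's rows must all carry the same class", call. = FALSE)
    }
    u
  }
  set.seed(as.integer(seed))
  learn_units <- character(0)
  counts <- list()
  for (cl in classes) {
    cl_units <- units$unit[units$class == cl]
    n <- length(cl_units)
    if (n < 3) stop("class '", cl, "' has fewer than 3 units", call. = FALSE)
    n_learn <- round_half_up(learning_fraction * n)
    if (n_learn < 1 || n - n_learn < 1) {
      stop("split leaves an empty side for class '", cl, "'", call. = FALSE)
    }
    learn_units <- c(learn_units, as.character(sample(cl_units)[seq_len(n_learn)]))
    counts[[cl]] <- c(learning = n_learn, test = n - n_learn)
  }
  unit_of_row <- if (is.null(subject_ids)) {
    as.character(seq_along(labels))
  } else {
    as.character(subject_ids)
  }
  learning <- which(unit_of_row %in% learn_units)
  list(
    learning = learning,
    test = setdiff(seq_along(labels), learning),
    counts = counts
  )
}

#' Fit a two-class Mahalanobis discriminant model
#'
#' Class centroids are the feature means; the pooled within-class
#' covariance is `((n1-1) S1 + (n2-1) S2) / (N - 2)`. When the covariance
#' is numerically singular (condition number above `cond_tol`) a ridge
#' `epsilon I` with `epsilon = 1e-6 trace(S) / p` is added before
#' inversion; tiny clinical panels on small samples can be collinear.
#'
#' @param x Numeric feature matrix (complete cases only).
#' @param y Class labels (2 classes, each with >= 2 rows).
#' @param cond_tol Condition-number threshold triggering the ridge.
#' @param ridge Override the ridge (0 disables it even for singular fits,
#'   in which case a pseudo-inverse would be required and an error is
#'   raised instead).
#' @return An object of class `mahalanobis_lda`: `classes`, `centroids`
#'   (class x feature), `cov`, `cov_inv`, `features`, `ridge`.
#' @export
fit_mahalanobis_lda <- function(x, y, cond_tol = 1e10, ridge = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2) stop("exactly 2 classes required", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs >= 2 rows", call. = FALSE)
  if (anyNA(x)) stop("feature matrix must be complete-case", call. = FALSE)
  zero_var <- colnames(x)[apply(x, 2, function(v) stats::var(v) == 0)]
  if (length(zero_var)) {
    stop("zero-variance feature(s): ", paste(zero_var, collapse = ", "),
      call. = FALSE
    )
  }
  x1 <- x[y == classes[1], , drop = FALSE]
  x2 <- x[y == classes[2], , drop = FALSE]
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  pooled <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  p <- ncol(x)
  eps <- 0
  cond <- kappa(pooled, exact = TRUE)
  if (is.null(ridge)) {
    if (!is.finite(cond) || cond > cond_tol) {
      eps <- 1e-6 * sum(diag(pooled)) / p
    }
  } else {
    eps <- ridge
  }
  sigma <- pooled + diag(eps, p)
  cov_inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(cov_inv)) {
    stop("pooled covariance is singular and the ridge is disabled", call. = FALSE)
  }
  structure(
    list(
      classes = classes,
      centroids = rbind(colMeans(x1), colMeans(x2)),
      cov = sigma,
      cov_inv = cov_inv,
      features = colnames(x),
      ridge = eps,
      n = c(n1, n2)
    ),
    class = "mahalanobis_lda"
  )
}

#' Squared Mahalanobis distances to both class centroids
#'
#' @param model A [fit_mahalanobis_lda()] model.
#' @param x Matrix (or vector) of observations with the model's features.
#' @return Matrix n x 2 of squared distances, columns named by class.
#' @export
mahalanobis_distances <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$features)) {
    stop("dimension mismatch: model expects ", length(model$features),
      " features",
      call. = FALSE
    )
  }
  d2 <- vapply(1:2, function(k) {
    stats::mahalanobis(x, model$centroids[k, ], model$cov_inv, inverted = TRUE)
  }, numeric(nrow(x)))
  d2 <- matrix(d2, ncol = 2, dimnames = list(NULL, model$classes))
  d2
}

#' Classify observations by minimal Mahalanobis distance
#'
#' Ties go deterministically to the first class of the model.
#'
#' @inheritParams mahalanobis_distances
#' @return Character vector of predicted class labels.
#' @export
classify <- function(model, x) {
  d2 <- mahalanobis_distances(model, x)
  model$classes[ifelse(d2[, 1] <= d2[, 2], 1, 2)]
}

#' Confusion counts and classification accuracy
#'
#' ACC = (TP + TN) / (TP + TN + FP + FN) with respect to a designated
#' positive class.
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive_class The label counted as positive.
#' @return List with `confusion` (tp, tn, fp, fn) and `acc` in \[0, 1\].
#' @export
accuracy <- function(pred, truth, positive_class) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth) || length(pred) < 1) {
    stop("pred and truth must be equal-length, non-empty", call. = FALSE)
  }
  labels <- unique(c(truth, positive_class))
  if (length(labels) > 2) stop("more than two classes present", call. = FALSE)
  if (any(!pred %in% labels)) {
    stop("prediction label outside the two classes", call. = FALSE)
  }
  tp <- sum(pred == positive_class & truth == positive_class)
  tn <- sum(pred != positive_class & truth != positive_class)
  fp <- sum(pred == positive_class & truth != positive_class)
  fn <- sum(pred != positive_class & truth == positive_class)
  list(
    confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
    acc = (tp + tn) / length(pred)
  )
}

#' @export
print.mahalanobis_lda <- function(x, ...) {
  cat(
    "<mahalanobis_lda> classes:", paste(x$classes, collapse = " vs "),
    "| features:", paste(x$features, collapse = ", "),
    "| ridge:", format(x$ridge), "\n"
  )
  invisible(x)
}
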