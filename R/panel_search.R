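# Exhaustive combinatorial panel evaluation: every candidate-variable
# subset is fed to the Mahalanobis discriminant on one shared
# learning/test split and ranked by test accuracy.

#' Number of non-empty variable subsets
#'
#' @param k Number of toggleable candidate variables (>= 1).
#' @return `2^k - 1`.
#' @examples
#' count_combinations(14) # 16383
#' @export
count_combinations <- function(k) {
  if (!is.finite(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  2^k - 1
}

#' Default candidate variables of the multi-parameter search
#'
#' The 14 toggleable variables of the cumulative-accuracy search over the
#' pre- vs post-treatment task: vaspin plus 13 metabolic, renal and
#' insulin-resistance indicators.
#'
#' @return Character vector of 14 column names.
#' @export
panel_candidates <- function() {
  c(
    "vaspin", "hba1c", "hdl", "ldl", "tg", "acr", "egfr", "glucose",
    "insulin", "quicki", "homa_ir", "homa_s", "homa_b", "egdr"
  )
}

# Rows, labels and split units for one classification task.
# healthy_vs_t2dm pools both patient visits into one class and splits by
# subject so both visits of a patient fall on the same side;
# pre_vs_post contrasts the two visits of the patients as independent
# groups (the study design; the pairing is deliberately ignored by the
# classifier) and splits by row.
panel_task_data <- function(data, task = c("healthy_vs_t2dm", "pre_vs_post")) {
  task <- match.arg(task)
  if (task == "healthy_vs_t2dm") {
    list(
      data = data,
      y = ifelse(data$group == "t2dm", "t2dm", "control"),
      subject_ids = data$subject_id,
      positive = "t2dm"
    )
  } else {
    d <- data[data$group == "t2dm", , drop = FALSE]
    list(
      data = d,
      y = as.character(d$visit),
      subject_ids = NULL,
      positive = "month6"
    )
  }
}

panel_result_row <- function(panel, task, acc, conf, n_learning, n_test,
                             seed, reason = NA_character_) {
  panel_size <- length(panel)
  tibble::tibble(
    panel = paste(panel, collapse = ","),
    size = panel_size,
    task = task,
    acc = acc,
    tp = conf[["tp"]], tn = conf[["tn"]], fp = conf[["fp"]], fn = conf[["fn"]],
    n_learning = n_learning, n_test = n_test,
    seed = seed,
    skipped = !is.na(reason),
    reason = reason
  )
}

eval_panel_on_split <- function(X, y, split, panel, positive) {
  cols <- match(panel, colnames(X))
  Xl <- X[split$learning, cols, drop = FALSE]
  Xt <- X[split$test, cols, drop = FALSE]
  model <- fit_mahalanobis_lda(Xl, y[split$learning])
  pred <- classify(model, Xt)
  accuracy(pred, y[split$test], positive)
}

#' Evaluate one diagnostic panel
#'
#' Runs the full chain for a single variable subset: complete-case
#' restriction, stratified 2/3-1/3 split, Mahalanobis discriminant fit on
#' the learning set, classification of the test set, and the accuracy
#' statistic. Insufficient complete cases yield a result row flagged
#' `skipped` rather than an error.
#'
#' @param data Cohort-with-indices tibble containing the panel columns.
#' @param panel Character vector of feature names (non-empty, no
#'   duplicates).
#' @param task `"healthy_vs_t2dm"` or `"pre_vs_post"`.
#' @param seed Split seed.
#' @return One-row tibble: panel, size, task, acc (percent), confusion
#'   counts, split sizes, seed, skipped, reason.
#' @export
evaluate_panel <- function(data, panel, task = "healthy_vs_t2dm", seed = 1) {
  if (length(panel) < 1 || anyDuplicated(panel)) {
    stop("panel must be non-empty without duplicates", call. = FALSE)
  }
  missing_cols <- setdiff(panel, names(data))
  if (length(missing_cols)) {
    stop("panel features absent from data: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  td <- panel_task_data(data, task)
  X <- as.matrix(td$data[, panel, drop = FALSE])
  ok <- stats::complete.cases(X)
  y <- td$y[ok]
  X <- X[ok, , drop = FALSE]
  sid <- if (is.null(td$subject_ids)) NULL else td$subject_ids[ok]
  if (min(table(y)) < 3) {
    return(panel_result_row(
      panel, task, NA_real_, c(tp = NA, tn = NA, fp = NA, fn = NA),
      NA_integer_, NA_integer_, seed,
      reason = "fewer than 3 complete cases in a class"
    ))
  }
  split <- stratified_split(y, seed = seed, subject_ids = sid)
  res <- eval_panel_on_split(X, y, split, panel, td$positive)
  panel_result_row(
    panel, task, 100 * res$acc, res$confusion,
    length(split$learning), length(split$test), seed
  )
}

make_report <- function(results, task, mode, anchors, candidates, seed) {
  done <- results[!results$skipped, , drop = FALSE]
  ranking <- done[order(-done$acc, done$size, done$panel), , drop = FALSE]
  curve <- tibble::tibble(
    order = seq_len(nrow(done)),
    acc = done$acc,
    cum_max_acc = cummax(done$acc)
  )
  best_by_size <- dplyr::summarise(
    dplyr::group_by(done, .data$size),
    acc = max(.data$acc), .groups = "drop"
  )
  best_by_size <- best_by_size[order(best_by_size$size), ]
  prior_best <- cummax(c(-Inf, best_by_size$acc))[seq_len(nrow(best_by_size))]
  pareto <- best_by_size[best_by_size$acc > prior_best, , drop = FALSE]
  structure(
    list(
      results = results, ranking = ranking, curve = curve, pareto = pareto,
      task = task, mode = mode, anchors = anchors,
      candidates = candidates, seed = seed
    ),
    class = "panel_search_report"
  )
}

#' @export
print.panel_search_report <- function(x, ...) {
  cat(
    "<panel_search_report> task:", x$task, "| mode:", x$mode,
    "|", nrow(x$results), "panels evaluated\n"
  )
  if (nrow(x$ranking)) {
    top <- x$ranking[1, ]
    cat(
      " best panel:", top$panel, sprintf("(ACC = %.1f%%)", top$acc), "\n"
    )
  }
  invisible(x)
}

#' Exhaustive panel search
#'
#' Evaluates every non-empty subset of the candidate variables
#' (`mode = "unanchored"`, `2^k - 1` panels) or every subset containing
#' all anchor variables (`mode = "anchored"`, `2^(k - a)` panels including
#' the anchors-only panel). All panels share one stratified split (same
#' seed) so that accuracy differences reflect the panels rather than split
#' noise; set `reseed_per_panel = TRUE` for a per-panel split sensitivity
#' mode. Enumeration follows the binary counting order of the candidate
#' list, which fixes the cumulative maximum-accuracy curve.
#'
#' @param data Cohort-with-indices tibble.
#' @param candidates Character vector of candidate variable names.
#' @param task `"healthy_vs_t2dm"` or `"pre_vs_post"`.
#' @param anchors Variables forced into every panel (must be a subset of
#'   `candidates`).
#' @param mode `"unanchored"` or `"anchored"`.
#' @param seed Split seed.
#' @param reseed_per_panel Draw a fresh split for every panel.
#' @return A `panel_search_report`: `results` (enumeration order),
#'   `ranking` (accuracy desc, then smaller panel, then lexicographic),
#'   `curve` (cumulative max accuracy) and `pareto` (best accuracy by
#'   panel size).
#' @export
exhaustive_search <- function(data, candidates = panel_candidates(),
                              task = "pre_vs_post",
                              anchors = character(0),
                              mode = c("unanchored", "anchored"),
                              seed = 1, reseed_per_panel = FALSE) {
  mode <- match.arg(mode)
  if (!length(candidates)) stop("candidate list is empty", call. = FALSE)
  if (anyDuplicated(candidates)) stop("duplicate candidates", call. = FALSE)
  if (length(bad <- setdiff(anchors, candidates))) {
    stop("anchors not in candidates: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (mode == "unanchored" && length(anchors)) {
    stop("anchors require mode = \"anchored\"", call. = FALSE)
  }
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    stop("candidate features absent from data: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }

  td <- panel_task_data(data, task)
  X <- as.matrix(td$data[, candidates, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- td$y[ok]
  sid <- if (is.null(td$subject_ids)) NULL else td$subject_ids[ok]
  if (min(table(y)) < 3) {
    stop("fewer than 3 complete cases in a class", call. = FALSE)
  }
  split <- stratified_split(y, seed = seed, subject_ids = sid)

  free <- if (mode == "anchored") setdiff(candidates, anchors) else candidates
  masks <- if (mode == "anchored") {
    0:(2^length(free) - 1)
  } else {
    1:(2^length(free) - 1)
  }
  n_panels <- length(masks)
  bits <- 2^(seq_along(free) - 1)

  acc <- numeric(n_panels)
  conf <- matrix(NA_integer_, n_panels, 4,
    dimnames = list(NULL, c("tp", "tn", "fp", "fn"))
  )
  panel_str <- character(n_panels)
  size <- integer(n_panels)
  for (i in seq_len(n_panels)) {
    subset <- free[bitwAnd(masks[i], bits) > 0]
    panel <- c(anchors, subset)
    if (reseed_per_panel) {
      split <- stratified_split(y, seed = seed + i, subject_ids = sid)
    }
    res <- eval_panel_on_split(X, y, split, panel, td$positive)
    acc[i] <- 100 * res$acc
    conf[i, ] <- res$confusion
    panel_str[i] <- paste(panel, collapse = ",")
    size[i] <- length(panel)
  }
  results <- tibble::tibble(
    panel = panel_str, size = size, task = task, acc = acc,
    tp = conf[, "tp"], tn = conf[, "tn"], fp = conf[, "fp"], fn = conf[, "fn"],
    n_learning = length(split$learning), n_test = length(split$test),
    seed = seed, skipped = FALSE, reason = NA_character_
  )
  make_report(results, task, mode, anchors, candidates, seed)
}

#' Fixed three-parameter panel suite
#'
#' Evaluates the study's printed list of 16 three-parameter panels: the
#' adropin/irisin/vaspin triple plus each adipokine combined with the five
#' indicator pairs (QUICKI, HOMA-IR), (ACR, eGFR), (HbA1c, eGDR),
#' (HOMA-B, HOMA-S) and (insulin, TG/HDL). All panels share one split.
#'
#' @inheritParams exhaustive_search
#' @return A `panel_search_report` with results in the printed order.
#' @export
three_parameter_suite <- function(data, task = "healthy_vs_t2dm", seed = 1) {
  adipokines <- c("adropin", "irisin", "vaspin")
  pairs <- list(
    c("quicki", "homa_ir"),
    c("acr", "egfr"),
    c("hba1c", "egdr"),
    c("homa_b", "homa_s"),
    c("insulin", "tg_hdl")
  )
  panels <- c(
    list(adipokines),
    unlist(lapply(pairs, function(p) lapply(adipokines, function(a) c(a, p))),
      recursive = FALSE
    )
  )
  results <- dplyr::bind_rows(lapply(
    panels, function(p) evaluate_panel(data, p, task = task, seed = seed)
  ))
  make_report(results, task, "fixed", character(0),
    unique(unlist(panels)), seed
  )
}

#' Minimal panels above an accuracy floor
#'
#' Among panels reaching at least `acc_floor` percent accuracy, returns
#' the ones of minimal size (all ties kept) - the smallest panel with the
#' highest attainable differentiating power.
#'
#' @param report A `panel_search_report`.
#' @param acc_floor Accuracy floor in percent.
#' @return Tibble of panel result rows (empty if the floor is
#'   unattainable).
#' @export
minimal_panels <- function(report, acc_floor) {
  stopifnot(inherits(report, "panel_search_report"))
  done <- report$results[!report$results$skipped, , drop = FALSE]
  hit <- done[!is.na(done$acc) & done$acc >= acc_floor, , drop = FALSE]
  if (!nrow(hit)) {
    return(hit)
  }
  hit <- hit[hit$size == min(hit$size), , drop = FALSE]
  hit[order(-hit$acc, hit$panel), ]
}
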