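# End-to-end pipeline: simulate -> indices -> summary tables ->
# correlations -> panel classification, with every artifact written to a
# run directory together with a manifest recording seed and configuration.

summary_vars_table1 <- function() {
  c(
    "age", "bmi", "whr", "glucose", "hba1c", "tg", "tc", "hdl", "ldl",
    "tg_hdl", "scr", "ucr", "ualb", "acr", "egfr", "insulin",
    "homa_ir", "homa_b", "homa_s", "quicki", "egdr", "sbp", "dbp"
  )
}

#' Render study-style summary tables
#'
#' Builds the two descriptive tables of the analysis: a clinical-
#' characteristics table (mean +/- SD per stratum and the percent change
#' following therapy computed from the two patient summary cells) and an
#' adipokine table (median and IQR, split All/F/M, percent change of the
#' medians).
#'
#' @param data Cohort tibble with index columns (see [add_indices()]).
#' @return List with tibbles `table1` and `table2`.
#' @export
render_summary_tables <- function(data) {
  strata <- list(
    control = filter_stratum(data, "control"),
    baseline = filter_stratum(data, "t2dm-baseline"),
    month6 = filter_stratum(data, "t2dm-month6")
  )
  if (any(vapply(strata, nrow, integer(1)) == 0)) {
    stop("cohort must contain both groups and both patient visits", call. = FALSE)
  }
  vars <- intersect(summary_vars_table1(), names(data))
  t1 <- dplyr::bind_rows(lapply(vars, function(v) {
    cells <- lapply(strata, function(s) summarize_values(s[[v]], "mean_sd"))
    tibble::tibble(
      variable = v,
      control_mean = cells$control$mean, control_sd = cells$control$sd,
      baseline_mean = cells$baseline$mean, baseline_sd = cells$baseline$sd,
      month6_mean = cells$month6$mean, month6_sd = cells$month6$sd,
      pct_change = percent_change(cells$baseline$mean, cells$month6$mean)
    )
  }))

  adipokines <- c("adropin", "irisin", "vaspin")
  rows <- list()
  for (v in adipokines) {
    for (sx in c("All", "F", "M")) {
      cells <- lapply(strata, function(s) {
        if (sx != "All") s <- s[s$sex == sx, , drop = FALSE]
        summarize_values(s[[v]], "median_iqr")
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, sex = sx,
        control_median = cells$control$median,
        control_q1 = cells$control$q1, control_q3 = cells$control$q3,
        baseline_median = cells$baseline$median,
        baseline_q1 = cells$baseline$q1, baseline_q3 = cells$baseline$q3,
        month6_median = cells$month6$median,
        month6_q1 = cells$month6$q1, month6_q3 = cells$month6$q3,
        pct_change = percent_change(cells$baseline$median, cells$month6$median)
      )
    }
  }
  list(table1 = t1, table2 = dplyr::bind_rows(rows))
}

pipeline_artifacts <- function() {
  c(
    "cohort.csv", "indices.csv", "table1_like.csv", "table2_like.csv",
    "table3_like.csv", "table4_like.csv", "report.json", "curve.csv",
    "manifest.json", "run.log"
  )
}

#' Run the full panel-discovery pipeline
#'
#' simulate -> indices -> summary tables -> correlation tables -> fixed
#' three-parameter suite -> exhaustive panel search, each stage's output
#' feeding the next and every artifact written to `out_dir`:
#' `cohort.csv`, `indices.csv`, `table1_like.csv`, `table2_like.csv`,
#' `table3_like.csv`, `table4_like.csv`, `report.json`, `curve.csv`,
#' `manifest.json` and `run.log`. Reruns with the same configuration and
#' seed produce identical tables.
#'
#' @param out_dir Run directory (created if absent).
#' @param seed Seed for cohort simulation and split.
#' @param spec [cohort_spec()] for the simulation stage.
#' @param candidates,anchors,search_mode,search_task Passed to
#'   [exhaustive_search()].
#' @param force Overwrite existing artifacts (default FALSE).
#' @return Invisibly, the run directory path.
#' @export
run_full_pipeline <- function(out_dir, seed = 42, spec = default_spec(),
                              candidates = panel_candidates(),
                              anchors = character(0),
                              search_mode = "unanchored",
                              search_task = "pre_vs_post",
                              force = FALSE) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  } else {
    existing <- intersect(pipeline_artifacts(), list.files(out_dir))
    if (length(existing) && !force) {
      stop("run directory already holds artifacts (",
        paste(existing, collapse = ", "),
        "); use force = TRUE to overwrite",
        call. = FALSE
      )
    }
  }
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_lines <<- c(log_lines, paste0("ERROR [", name, "] ", conditionMessage(e)))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      manifest <- list(
        seed = seed, status = "failed", failed_stage = name,
        error = conditionMessage(e)
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE
      )
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  note("stage simulate: seed ", seed)
  cohort <- stage("simulate", simulate_cohort(spec, seed = seed))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  note("stage indices: ", nrow(cohort), " subject-visits")
  indices <- stage("indices", add_indices(cohort))
  readr::write_csv(indices, file.path(out_dir, "indices.csv"), progress = FALSE)

  note("stage summaries")
  tables <- stage("summaries", render_summary_tables(indices))
  readr::write_csv(tables$table1, file.path(out_dir, "table1_like.csv"),
    progress = FALSE
  )
  readr::write_csv(tables$table2, file.path(out_dir, "table2_like.csv"),
    progress = FALSE
  )

  note("stage correlations")
  cor_params <- c(
    "weight", "bmi", "acr", "egfr", "insulin", "homa_ir", "homa_s",
    "homa_b", "quicki", "egdr", "glucose", "hba1c", "tc", "hdl", "ldl",
    "tg", "tg_hdl"
  )
  t3 <- stage("correlations", dplyr::bind_rows(
    correlation_table(indices, c("adropin", "irisin", "vaspin"), cor_params,
      stratum = "t2dm-baseline"
    ),
    correlation_table(indices, c("adropin", "irisin", "vaspin"), cor_params,
      stratum = "t2dm-month6"
    )
  ))
  readr::write_csv(t3, file.path(out_dir, "table3_like.csv"), progress = FALSE)

  note("stage three-parameter suite")
  t4 <- stage("three_parameter", dplyr::bind_rows(
    three_parameter_suite(indices, task = "healthy_vs_t2dm", seed = seed)$results,
    three_parameter_suite(indices, task = "pre_vs_post", seed = seed)$results
  ))
  readr::write_csv(t4, file.path(out_dir, "table4_like.csv"), progress = FALSE)

  note(
    "stage panel search: ", length(candidates), " candidates, mode ",
    search_mode
  )
  report <- stage("panel_search", exhaustive_search(
    indices,
    candidates = candidates, task = search_task,
    anchors = anchors, mode = search_mode, seed = seed
  ))
  readr::write_csv(report$curve, file.path(out_dir, "curve.csv"),
    progress = FALSE
  )
  jsonlite::write_json(
    list(
      task = report$task, mode = report$mode, seed = seed,
      candidates = report$candidates, anchors = report$anchors,
      n_panels = nrow(report$results),
      results = report$results,
      pareto = report$pareto
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )

  config <- list(
    seed = seed, candidates = candidates, anchors = anchors,
    search_mode = search_mode, search_task = search_task
  )
  manifest <- list(
    seed = seed,
    status = "complete",
    package_version = as.character(utils::packageVersion("adipopanel")),
    config = config,
    config_hash = rlang::hash(config),
    artifacts = setdiff(pipeline_artifacts(), c("manifest.json", "run.log"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  note("pipeline complete")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
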