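#' Pipeline stage: simulate a synthetic cohort to disk
#'
#' Writes `patients.csv`, `events.csv` and a `provenance.json` (scenario,
#' seed, package version) into `out_dir`. Output is byte-deterministic given
#' the seed.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory, created if absent.
#' @param seed optional integer overriding the scenario seed.
#' @return invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config = default_scenario(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_cohort(config)
  paths <- list(
    patients = file.path(out_dir, "patients.csv"),
    events = file.path(out_dir, "events.csv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  readr::write_csv(sim$patients, paths$patients, progress = FALSE)
  readr::write_csv(sim$events, paths$events, progress = FALSE)
  prov <- list(
    scenario = unclass(config),
    package = "carematrix",
    version = as.character(utils::packageVersion("carematrix")),
    n_patients = nrow(sim$patients),
    n_events = nrow(sim$events)
  )
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Pipeline stage: score a patient/event table pair
#'
#' Reads and validates the two tables, attaches events (dropped out-of-range
#' events are reported), scores every patient on the three matrix tracks and
#' writes `scores.csv`. Validation failures raise before any output is
#' written, so there is never a partial scores file.
#'
#' @param patients_path,events_path input CSV paths.
#' @param out_path output path for the scores CSV.
#' @param rubric_path optional path to an alternative rubric YAML.
#' @return invisibly, the scored tibble.
#' @export
run_score <- function(patients_path, events_path, out_path,
                      rubric_path = NULL) {
  rubric <- if (is.null(rubric_path)) default_rubric() else read_rubric(rubric_path)
  patients <- read_patients(patients_path)
  events <- read_events(events_path)
  patients <- attach_events(patients, events)
  scores <- score_cohort(patients, rubric)
  message(sprintf("scored %d patient(s) from %d input row(s)",
                  nrow(scores), nrow(patients)))
  write_scores(scores, out_path)
  invisible(scores)
}

#' Pipeline stage: demographic and score summaries
#'
#' Writes a demographic table (per-cohort integer percentages plus pooled
#' two-decimal percentages), per-cohort and pooled score summaries for all
#' three tracks, and a short plain-text report.
#'
#' @param patients_path,scores_path input CSV paths.
#' @param out_dir output directory, created if absent.
#' @return invisibly, a list with `demographics` and `score_summary` tibbles.
#' @export
run_summarize <- function(patients_path, scores_path, out_dir) {
  patients <- read_patients(patients_path)
  scores <- read_scores(scores_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  demo <- demographics_table(patients)
  metrics <- c(swa = "swa_level", pba = "pba_level", combined = "combined_level")
  summaries <- list()
  for (m in names(metrics)) {
    col <- metrics[[m]]
    for (co in unique(scores$cohort)) {
      s <- summarize_scores(scores[[col]][scores$cohort == co], cohort = co)
      s$metric <- m
      summaries[[length(summaries) + 1L]] <- s
    }
    s <- summarize_scores(scores[[col]], cohort = "pooled")
    s$metric <- m
    summaries[[length(summaries) + 1L]] <- s
  }
  score_summary <- dplyr::bind_rows(summaries)
  score_summary <- score_summary[c("metric", setdiff(names(score_summary), "metric"))]

  readr::write_csv(demo, file.path(out_dir, "demographics.csv"), progress = FALSE)
  readr::write_csv(score_summary, file.path(out_dir, "score_summary.csv"),
                   progress = FALSE)

  lines <- character(0)
  pooled <- demo[demo$cohort == "pooled", ]
  for (dim_name in unique(pooled$dimension)) {
    sub <- pooled[pooled$dimension == dim_name & pooled$n > 0, ]
    top <- sub[which.max(sub$n), ]
    lines <- c(lines, sprintf("%s: most frequent %s (%.2f%%, n = %d)",
                              dim_name, top$category, top$pct, top$n))
  }
  for (i in seq_len(nrow(score_summary))) {
    r <- score_summary[i, ]
    lines <- c(lines, sprintf(
      "%s score, %s: mean %.2f (SD = %.2f; %.2f-%.2f, 95%% CI), n = %d",
      r$metric, r$cohort, r$mean, r$sd, r$ci_low, r$ci_high, r$n))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(list(demographics = demo, score_summary = score_summary))
}

#' Pipeline stage: compare two cohorts on one matrix track
#'
#' Summarizes both cohorts and runs the pooled one-tailed t-test. The JSON
#' report keeps full precision; the text report rounds to two decimals.
#'
#' @param scores_path scores CSV path.
#' @param metric `"combined"` (default), `"swa"` or `"pba"`.
#' @param groups character vector of the two cohort labels, first then second;
#'   the alternative is directional for the second cohort.
#' @param direction `"greater"` (default) or `"less"`.
#' @param out_dir optional output directory for `comparison.json` and
#'   `comparison.txt`.
#' @return invisibly, a list with `summaries` and `comparison` tibbles.
#' @export
run_compare <- function(scores_path, metric = c("combined", "swa", "pba"),
                        groups, direction = c("greater", "less"),
                        out_dir = NULL) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  scores <- read_scores(scores_path)
  stopifnot(length(groups) == 2L)
  available <- unique(scores$cohort)
  unknown <- setdiff(groups, available)
  if (length(unknown)) {
    stop("unknown cohort label(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  col <- paste0(metric, "_level")
  a <- scores[[col]][scores$cohort == groups[1L]]
  b <- scores[[col]][scores$cohort == groups[2L]]
  summaries <- dplyr::bind_rows(
    summarize_scores(a, cohort = groups[1L]),
    summarize_scores(b, cohort = groups[2L])
  )
  cmp <- compare_cohorts(a, b, direction = direction)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(metric = metric, groups = as.list(groups),
           summaries = summaries, comparison = cmp),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
    )
    txt <- c(
      sprintf("Comparison of %s matrix scores: %s vs %s (one-tailed, %s)",
              metric, groups[1L], groups[2L], direction),
      sprintf("  %s: mean %.2f (SD = %.2f; %.2f-%.2f, 95%% CI), n = %d",
              summaries$cohort, summaries$mean, summaries$sd,
              summaries$ci_low, summaries$ci_high, summaries$n),
      sprintf("  t = %.2f, df = %d, one-tailed p = %.4f (%s at alpha = 0.05)",
              cmp$t_statistic, cmp$df, cmp$p_one_tailed,
              if (cmp$significant) "significant" else "not significant")
    )
    writeLines(txt, file.path(out_dir, "comparison.txt"))
  }
  invisible(list(summaries = summaries, comparison = cmp))
}
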