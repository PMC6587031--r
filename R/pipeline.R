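#' @keywords internal
#' @useDynLib mrtraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Run the full analysis on a feature table
#'
#' Two-stage feature selection, the Rad-score on the final features, and the
#' 20-classifier repeated-CV comparison.
#'
#' @param table a [feature_table()].
#' @param config a [pipeline_config()].
#' @param auto_tune passed to [two_stage_select()].
#' @return List with `selection`, `rad_score`, `report`, `best`.
#' @export
run_table_analysis <- function(table, config = pipeline_config(),
                               auto_tune = FALSE) {
  sel <- two_stage_select(table, config, auto_tune = auto_tune)
  rs <- rad_score(table, sel)
  y <- task_labels(table$labels, config$task)
  report <- repeated_cv_accuracy(
    table$values[, sel$final_features, drop = FALSE], y,
    build_model_zoo(config$task),
    cv_plan(config$cv_folds, config$cv_rounds, config$seed))
  list(selection = sel, rad_score = rs, report = report,
       best = best_model(report))
}

#' Run the full analysis on a phantom image cohort
#'
#' Generates the cohort, extracts the 2,498-column catalog, and runs
#' [run_table_analysis()].
#'
#' @param cohort_spec a [cohort_spec()].
#' @param config a [pipeline_config()].
#' @param auto_tune passed to [two_stage_select()].
#' @return As [run_table_analysis()], plus the `table`.
#' @export
run_phantom_analysis <- function(cohort_spec, config = pipeline_config(),
                                 auto_tune = FALSE) {
  cohort <- generate_image_cohort(cohort_spec)
  table <- extract_features(cohort, config$n_bins)
  out <- run_table_analysis(table, config, auto_tune = auto_tune)
  out$table <- table
  out
}
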