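#' Pipeline configuration
#'
#' Bundles every tunable of the selection and evaluation stages. Defaults
#' follow the published analysis: elliptical acceptance factors (0.6, 0.85)
#' for the four-subtype task and (0.54, 0.76) for TN vs. non-TN, top-40
#' rank-fusion shortlist, |Pearson r| > 0.4 pruning down to 20 (four-class)
#' or 8 (binary) final features, and stratified 5-fold cross-validation
#' repeated for 10 rounds.
#'
#' @param task `"four_class"` or `"tn_binary"`.
#' @param acceptance_factors length-2 numeric (a, b) in (0, 1]; `NULL` picks
#'   the task default.
#' @param fine_top_k shortlist size after rank fusion.
#' @param corr_threshold absolute Pearson correlation above which a
#'   lower-ranked feature is pruned.
#' @param final_feature_count target size of the final feature set; `NULL`
#'   picks the task default (20 four-class, 8 binary).
#' @param cv_folds,cv_rounds cross-validation folds (>= 2) and repeats.
#' @param seed integer seed governing every stochastic stage.
#' @param n_bins gray-level bin count for texture discretization.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(task = c("four_class", "tn_binary"),
                            acceptance_factors = NULL,
                            fine_top_k = 40,
                            corr_threshold = 0.4,
                            final_feature_count = NULL,
                            cv_folds = 5, cv_rounds = 10,
                            seed = 1L, n_bins = 32L) {
  task <- match.arg(task)
  if (is.null(acceptance_factors))
    acceptance_factors <- if (task == "four_class") c(0.6, 0.85) else c(0.54, 0.76)
  if (is.null(final_feature_count))
    final_feature_count <- if (task == "four_class") 20L else 8L
  a <- acceptance_factors[1]; b <- acceptance_factors[2]
  if (!(a > 0 && a <= 1 && b > 0 && b <= 1))
    stop("acceptance factors must lie in (0, 1]")
  if (!(corr_threshold > 0 && corr_threshold < 1))
    stop("`corr_threshold` must lie in (0, 1)")
  if (cv_folds < 2) stop("`cv_folds` must be >= 2")
  structure(list(task = task,
                 acceptance_factors = c(a = a, b = b),
                 fine_top_k = as.integer(fine_top_k),
                 corr_threshold = corr_threshold,
                 final_feature_count = as.integer(final_feature_count),
                 cv_folds = as.integer(cv_folds),
                 cv_rounds = as.integer(cv_rounds),
                 seed = as.integer(seed),
                 n_bins = as.integer(n_bins)),
            class = "pipeline_config")
}

#' Study-population exclusion arithmetic
#'
#' Applies the cohort exclusion counts of the study design to the number of
#' enrolled patients. The defaults encode the published cohort: 190
#' consecutive biopsy-proven invasive ductal carcinoma patients, excluding
#' prior malignancy (5), neoadjuvant chemotherapy before MR (31), lesions
#' under 1 cm (16), poor DWI fat saturation (3) and postcontrast slice-count
#' discordance (1), leaving 134.
#'
#' @param n_enrolled number of enrolled patients.
#' @param exclusions named integer vector of exclusion counts.
#' @return List with `n_enrolled`, `exclusions`, `n_excluded`, `n_final`.
#' @export
apply_cohort_exclusions <- function(
    n_enrolled = 190L,
    exclusions = c(prior_malignancy = 5L,
                   neoadjuvant_chemotherapy = 31L,
                   lesion_under_1cm = 16L,
                   poor_dwi_fat_saturation = 3L,
                   slice_count_discordance = 1L)) {
  exclusions <- as.integer(exclusions) |> stats::setNames(names(exclusions))
  if (any(exclusions < 0)) stop("exclusion counts must be non-negative")
  n_excluded <- sum(exclusions)
  if (n_excluded > n_enrolled)
    stop("exclusions exceed the enrolled count")
  list(n_enrolled = as.integer(n_enrolled),
       exclusions = exclusions,
       n_excluded = as.integer(n_excluded),
       n_final = as.integer(n_enrolled - n_excluded))
}

log_msg <- function(fmt, ...) {
  message(sprintf("[mrtraj %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
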