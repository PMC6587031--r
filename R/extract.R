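#' Extract the static (shape + texture) feature table of a cohort
#'
#' Per subject: 14 shape features on the first-postcontrast DCE mask,
#' 92 texture features on each of the 6 DCE phases (552) and each of the
#' 3 DWI b-value volumes (276) — 842 static columns. The whole-tumor mask of
#' each modality is propagated (identically) to every volume of its series.
#'
#' @param cohort list of [mr_subject()]s.
#' @param n_bins gray-level bin count for texture discretization.
#' @return A [feature_table()] with 842 columns and group metadata
#'   `DCE_shape` / `DCE_texture` / `DWI_texture`.
#' @export
extract_static_features <- function(cohort, n_bins = 32L) {
  stopifnot(length(cohort) >= 1,
            all(vapply(cohort, inherits, TRUE, "mr_subject")))
  ts <- texture_feature_set()

  one_subject <- function(s) {
    shape <- compute_shape_features(s$dce_mask)
    dce_masks <- propagate_mask(s$dce_mask, s$dce)
    dce <- unlist(lapply(seq_along(s$dce$volumes), function(k)
      compute_texture_features(s$dce$volumes[[k]], dce_masks[[k]], n_bins)))
    dwi_masks <- propagate_mask(s$dwi_mask, s$dwi)
    dwi <- unlist(lapply(seq_along(s$dwi$volumes), function(k)
      compute_texture_features(s$dwi$volumes[[k]], dwi_masks[[k]], n_bins)))
    c(shape, dce, dwi)
  }
  rows <- lapply(cohort, function(s) {
    r <- try(one_subject(s), silent = TRUE)
    if (inherits(r, "try-error"))
      stop("feature extraction failed for subject ", s$id, ": ",
           attr(r, "condition")$message)
    r
  })
  values <- do.call(rbind, rows)

  dce_tags <- vapply(cohort[[1]]$dce$volumes, function(v) v$axis_label, "")
  dwi_tags <- vapply(cohort[[1]]$dwi$volumes, function(v) v$axis_label, "")
  meta <- rbind(
    new_feature_meta(paste0("DCE_shape__", shape_feature_set()),
                     "DCE_shape", dce_tags[2], shape_feature_set()),
    do.call(rbind, lapply(dce_tags, function(tag)
      new_feature_meta(paste0(tag, "__", ts$feature),
                       "DCE_texture", tag, ts$feature))),
    do.call(rbind, lapply(dwi_tags, function(tag)
      new_feature_meta(paste0(tag, "__", ts$feature),
                       "DWI_texture", tag, ts$feature)))
  )
  feature_table(values,
                vapply(cohort, function(s) s$id, ""),
                vapply(cohort, function(s) s$label, ""),
                meta)
}

#' Append the sequential (trajectory) feature columns
#'
#' For each of the 92 base texture features, the per-subject trajectory
#' across the 6 DCE phases yields 10 sequential statistics (920 columns)
#' and across the 3 DWI b-values 8 statistics (736 columns; kurtosis and
#' entropy dropped), completing the 2,498-column catalog:
#' 14 + 552 + 920 + 276 + 736.
#'
#' @param static_table the 842-column [feature_table()] from
#'   [extract_static_features()].
#' @return The augmented [feature_table()] (2,498 columns).
#' @export
assemble_sequential <- function(static_table) {
  stopifnot(inherits(static_table, "feature_table"))
  meta <- static_table$meta
  ts <- texture_feature_set()
  n <- nrow(static_table$values)

  build_modality <- function(group_in, group_out, axis_kind) {
    stats_set <- sequential_stat_set(axis_kind)
    per_subj <- setdiff(stats_set, c("kendall_tau_b", "conservation",
                                     "stability", "dispersion"))
    sources <- unique(meta$source[meta$group == group_in])
    cols <- list(); metas <- list()
    for (f in ts$feature) {
      sel <- meta$group == group_in & meta$base_feature == f
      if (sum(sel) != length(sources))
        stop("missing acquisition for base feature ", f)
      M <- static_table$values[, meta$name[sel], drop = FALSE]
      vals <- matrix(NA_real_, n, length(stats_set),
                     dimnames = list(NULL, stats_set))
      for (i in seq_len(n))
        vals[i, per_subj] <- per_subject_stats(M[i, ], per_subj)
      ia <- cohort_interactive_all(M)
      vals[, "kendall_tau_b"] <- ia$kendall_tau_b
      vals[, "conservation"] <- ia$conservation
      vals[, "stability"] <- ia$stability
      vals[, "dispersion"] <- ia$dispersion
      cols[[f]] <- vals
      metas[[f]] <- new_feature_meta(
        paste0(group_out, "__", f, "__", stats_set),
        group_out, "trajectory", f, stats_set)
    }
    list(values = do.call(cbind, cols), meta = do.call(rbind, metas))
  }

  dce <- build_modality("DCE_texture", "DCE_sequential", "DCE_time")
  dwi <- build_modality("DWI_texture", "DWI_sequential", "DWI_bvalue")
  feature_table(cbind(static_table$values, dce$values, dwi$values),
                static_table$subject_ids, static_table$labels,
                rbind(meta, dce$meta, dwi$meta))
}

#' Extract the full 2,498-column feature catalog of a cohort
#'
#' Convenience wrapper: static extraction, sequential assembly, and the
#' zero-imputation of any non-finite cells.
#'
#' @inheritParams extract_static_features
#' @return A [feature_table()] with 2,498 columns.
#' @export
extract_features <- function(cohort, n_bins = 32L) {
  impute_nonfinite(assemble_sequential(extract_static_features(cohort, n_bins)))
}
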