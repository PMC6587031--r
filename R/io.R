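#' Read one subject's NIfTI volumes and masks
#'
#' Loads 6 DCE phases, 3 DWI b-value volumes and one whole-tumor mask per
#' modality, validates grid consistency and series lengths, and returns a
#' validated [mr_subject()].
#'
#' @param paths named list with character vectors `dce` (6 files, phase
#'   order), `dwi` (3 files, b-value order), and scalars `dce_mask`,
#'   `dwi_mask`.
#' @param id subject identifier.
#' @param label subtype label, one of [subtype_levels()].
#' @param b_values DWI b-values in s/mm^2 matching the `dwi` file order.
#' @return An [mr_subject()].
#' @export
read_subject <- function(paths, id, label, b_values = c(50, 400, 800)) {
  need <- c("dce", "dwi", "dce_mask", "dwi_mask")
  if (!all(need %in% names(paths)))
    stop("`paths` must have elements: ", paste(need, collapse = ", "))
  if (length(paths$dce) != 6L)
    stop("a DCE series requires 6 files (1 pre- + 5 post-contrast), got ",
         length(paths$dce))
  if (length(paths$dwi) != 3L)
    stop("a DWI series requires 3 files (one per b-value), got ",
         length(paths$dwi))
  all_paths <- c(paths$dce, paths$dwi, paths$dce_mask, paths$dwi_mask)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))

  read_vol <- function(p, tag) {
    img <- RNifti::readNifti(p)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
    image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                 spacing = sp, origin = org, axis_label = tag)
  }
  dce_tags <- paste0("DCE_phase", 0:5)
  dwi_tags <- paste0("DWI_b", b_values)
  dce <- image_series(mapply(read_vol, paths$dce, dce_tags, SIMPLIFY = FALSE),
                      "DCE_time", 0:5)
  dwi <- image_series(mapply(read_vol, paths$dwi, dwi_tags, SIMPLIFY = FALSE),
                      "DWI_bvalue", b_values)
  mvol <- read_vol(paths$dce_mask, "DCE_mask")
  dce_mask <- tumor_mask(mvol$voxels > 0, mvol$spacing, mvol$origin)
  mvol <- read_vol(paths$dwi_mask, "DWI_mask")
  dwi_mask <- tumor_mask(mvol$voxels > 0, mvol$spacing, mvol$origin)
  mr_subject(id, dce, dwi, dce_mask, dwi_mask, label)
}

#' Write one subject to NIfTI files
#'
#' Writes the 9 volumes and 2 masks of a subject under `dir`, named
#' `<id>_<tag>.nii.gz`, and returns the path set in the layout accepted by
#' [read_subject()].
#'
#' @param subject an [mr_subject()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "mr_subject"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(vox, spacing, tag) {
    p <- file.path(dir, paste0(subject$id, "_", tag, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vox + 0, pixdim = spacing), p)
    p
  }
  dce <- vapply(subject$dce$volumes,
                function(v) wr(v$voxels, v$spacing, v$axis_label), "")
  dwi <- vapply(subject$dwi$volumes,
                function(v) wr(v$voxels, v$spacing, v$axis_label), "")
  paths <- list(
    dce = unname(dce), dwi = unname(dwi),
    dce_mask = wr(subject$dce_mask$voxels, subject$dce_mask$spacing, "DCE_mask"),
    dwi_mask = wr(subject$dwi_mask$voxels, subject$dwi_mask$spacing, "DWI_mask")
  )
  invisible(paths)
}

#' Construct a feature table
#'
#' Subjects-by-features matrix with per-column provenance: feature group
#' (shape / texture / sequential, per modality), source acquisition (or
#' `"trajectory"`), base texture feature, and sequential statistic.
#'
#' @param values numeric matrix, one row per subject.
#' @param subject_ids character, one per row.
#' @param labels subtype labels, one per row.
#' @param meta data.frame with columns `name`, `group`, `source`,
#'   `base_feature`, `statistic`; one row per column of `values`;
#'   `name` must be unique.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, subject_ids, labels, meta) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("feature table must have at least one subject")
  if (length(subject_ids) != nrow(values) || length(labels) != nrow(values))
    stop("subject_ids and labels must match the number of rows")
  need <- c("name", "group", "source", "base_feature", "statistic")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("`meta` must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  if (nrow(meta) != ncol(values))
    stop("meta rows must match value columns")
  if (anyDuplicated(meta$name))
    stop("duplicate feature names: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  colnames(values) <- meta$name
  structure(list(values = values,
                 subject_ids = as.character(subject_ids),
                 labels = as.character(labels),
                 meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d subjects x %d features>\n",
              nrow(x$values), ncol(x$values)))
  print(table(factor(x$meta$group)))
  invisible(x)
}

#' Replace non-finite feature values by zero
#'
#' Undefined statistics on degenerate ROIs (e.g. skewness of a constant
#' region) are imputed to 0 — the neutral value after z-scoring — with a
#' warning listing how many cells were touched.
#'
#' @param table a [feature_table()].
#' @return The table with all values finite.
#' @export
impute_nonfinite <- function(table) {
  bad <- !is.finite(table$values)
  if (any(bad)) {
    warning(sprintf("imputed %d non-finite feature values to 0", sum(bad)))
    table$values[bad] <- 0
  }
  table
}

#' Write / read a feature table (CSV + JSON metadata sidecar)
#'
#' The CSV holds `subject_id`, `label`, then one column per feature; the
#' sidecar `<path>.meta.json` holds the column provenance. Round-trip is
#' lossless up to text precision (values are written with full precision).
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subject_ids, label = table$labels,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(table$values)
  names(vals) <- table$meta$name
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  jsonlite::write_json(table$meta, paste0(path, ".meta.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("feature table is empty (0 subjects)")
  if (!all(c("subject_id", "label") %in% names(df)))
    stop("malformed header: need subject_id and label columns")
  feat_cols <- setdiff(names(df), c("subject_id", "label"))
  if (anyDuplicated(feat_cols))
    stop("duplicate feature column id(s): ",
         paste(unique(feat_cols[duplicated(feat_cols)]), collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  if (!identical(as.character(meta$name), feat_cols))
    stop("metadata sidecar does not match CSV columns")
  feature_table(as.matrix(df[, feat_cols, drop = FALSE]),
                df$subject_id, df$label, meta)
}

new_feature_meta <- function(name, group, source, base_feature = "",
                             statistic = "") {
  data.frame(name = name, group = group, source = source,
             base_feature = base_feature, statistic = statistic,
             stringsAsFactors = FALSE)
}
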