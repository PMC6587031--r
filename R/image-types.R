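#' Construct a 3D image volume
#'
#' A single 3D acquisition: a real-valued voxel array with its grid geometry
#' and an acquisition tag (e.g. `"DCE_phase0"` or `"DWI_b800"`).
#'
#' @param voxels 3D numeric array of voxel values; all values must be finite.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm;
#'   strictly positive.
#' @param origin numeric length-3, world coordinates of voxel (0,0,0) in mm.
#' @param axis_label character scalar tagging the acquisition.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axis_label = "") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  structure(
    list(voxels = voxels, spacing = spacing,
         origin = as.numeric(origin), axis_label = as.character(axis_label)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s: %s voxels, spacing %s mm>\n",
              x$axis_label, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Construct an ordered image series
#'
#' An ordered stack of co-registered volumes along an acquisition axis:
#' DCE time points (6 phases) or DWI b-values (3 values). All volumes must
#' share the same grid and the axis values must be strictly increasing.
#'
#' @param volumes list of [image_volume()] objects.
#' @param axis_kind `"DCE_time"` or `"DWI_bvalue"`.
#' @param axis_values numeric, strictly increasing; phase indices 0..5 for
#'   DCE, b-values in s/mm^2 for DWI.
#' @return An object of class `image_series`.
#' @export
image_series <- function(volumes, axis_kind = c("DCE_time", "DWI_bvalue"),
                         axis_values = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (!length(volumes) || !all(vapply(volumes, inherits, TRUE, "image_volume")))
    stop("`volumes` must be a non-empty list of image_volume objects")
  n_req <- if (axis_kind == "DCE_time") 6L else 3L
  if (length(volumes) != n_req)
    stop(sprintf("a %s series requires exactly %d volumes, got %d",
                 axis_kind, n_req, length(volumes)))
  if (is.null(axis_values))
    axis_values <- if (axis_kind == "DCE_time") 0:5 else c(50, 400, 800)
  axis_values <- as.numeric(axis_values)
  if (length(axis_values) != length(volumes) || any(diff(axis_values) <= 0))
    stop("`axis_values` must be strictly increasing, one per volume")
  for (v in volumes[-1])
    if (!same_grid(volumes[[1]], v))
      stop("all volumes in a series must share grid shape, spacing and origin")
  structure(list(volumes = volumes, axis_kind = axis_kind,
                 axis_values = axis_values),
            class = "image_series")
}

#' Construct a whole-tumor binary mask
#'
#' @param voxels 3D array coercible to logical; at least one foreground voxel.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  vox <- array(as.logical(voxels) & !is.na(voxels), dim = dim(voxels))
  if (!any(vox))
    stop("mask must contain at least one foreground voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  structure(list(voxels = vox, spacing = spacing, origin = as.numeric(origin)),
            class = "tumor_mask")
}

mask_matches_series <- function(mask, series) {
  v1 <- series$volumes[[1]]
  identical(dim(mask$voxels), dim(v1$voxels)) &&
    isTRUE(all.equal(mask$spacing, v1$spacing)) &&
    isTRUE(all.equal(mask$origin, v1$origin))
}

#' Breast cancer IHC subtype levels
#'
#' Factor levels used throughout: Luminal A, Luminal B, HER2-positive and
#' triple negative.
#' @return Character vector of the four subtype codes.
#' @export
subtype_levels <- function() c("LuminalA", "LuminalB", "HER2pos", "TN")

#' Construct a subject (one patient's multiparametric series)
#'
#' @param id subject identifier.
#' @param dce DCE [image_series()] (6 phases).
#' @param dwi DWI [image_series()] (3 b-values).
#' @param dce_mask,dwi_mask whole-tumor [tumor_mask()] per modality, on the
#'   exact grid of the corresponding series.
#' @param label one of [subtype_levels()].
#' @return An object of class `mr_subject`.
#' @export
mr_subject <- function(id, dce, dwi, dce_mask, dwi_mask, label) {
  stopifnot(inherits(dce, "image_series"), inherits(dwi, "image_series"),
            inherits(dce_mask, "tumor_mask"), inherits(dwi_mask, "tumor_mask"))
  if (dce$axis_kind != "DCE_time" || dwi$axis_kind != "DWI_bvalue")
    stop("`dce` must be a DCE_time series and `dwi` a DWI_bvalue series")
  if (!mask_matches_series(dce_mask, dce))
    stop("DCE mask grid does not match the DCE series grid")
  if (!mask_matches_series(dwi_mask, dwi))
    stop("DWI mask grid does not match the DWI series grid")
  label <- as.character(label)
  if (!label %in% subtype_levels())
    stop("`label` must be one of: ", paste(subtype_levels(), collapse = ", "))
  structure(list(id = as.character(id), dce = dce, dwi = dwi,
                 dce_mask = dce_mask, dwi_mask = dwi_mask, label = label),
            class = "mr_subject")
}

#' @export
print.mr_subject <- function(x, ...) {
  cat(sprintf("<mr_subject %s [%s]: DCE %d phases, DWI b = %s>\n",
              x$id, x$label, length(x$dce$volumes),
              paste(x$dwi$axis_values, collapse = "/")))
  invisible(x)
}

#' Propagate a whole-tumor mask across a series
#'
#' The segmentation drawn on one acquisition (first postcontrast for DCE,
#' b = 800 for DWI) is shared by every other volume of the series; on a
#' common co-registered grid propagation is the identity, so each volume
#' receives an identical copy of the mask.
#'
#' @param mask a [tumor_mask()].
#' @param series an [image_series()] on the same grid.
#' @return A list with one `tumor_mask` per volume, all identical to `mask`.
#' @export
propagate_mask <- function(mask, series) {
  stopifnot(inherits(mask, "tumor_mask"), inherits(series, "image_series"))
  if (!mask_matches_series(mask, series))
    stop("mask grid does not match series grid")
  rep(list(mask), length(series$volumes))
}
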