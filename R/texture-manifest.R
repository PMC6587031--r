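#' The frozen 92-feature texture manifest
#'
#' The texture catalog is pinned to the standard radiomics families —
#' 18 first-order, 23 gray-level co-occurrence (GLCM), 16 run-length
#' (GLRLM), 16 size-zone (GLSZM), 14 dependence (GLDM) and 5
#' neighbourhood-tone-difference (NGTDM) features — in a frozen order, since
#' catalog identity (and the 552/276/920/736 group counts) depends on it.
#'
#' @return data.frame with columns `family` and `name`, 92 rows.
#' @export
texture_feature_set <- function() {
  fo <- c("energy", "total_energy", "entropy", "minimum", "percentile10",
          "percentile90", "maximum", "mean", "median", "interquartile_range",
          "range", "mean_absolute_deviation", "robust_mad",
          "root_mean_squared", "skewness", "kurtosis", "variance",
          "uniformity")
  glcm <- c("autocorrelation", "joint_average", "cluster_prominence",
            "cluster_shade", "cluster_tendency", "contrast", "correlation",
            "difference_average", "difference_entropy", "difference_variance",
            "id", "idm", "idmn", "idn", "imc1", "imc2", "inverse_variance",
            "joint_energy", "joint_entropy", "maximum_probability",
            "sum_average", "sum_entropy", "sum_of_squares")
  glrlm <- c("short_run_emphasis", "long_run_emphasis",
             "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
             "run_length_nonuniformity", "run_length_nonuniformity_normalized",
             "run_percentage", "gray_level_variance", "run_variance",
             "run_entropy", "low_gray_level_run_emphasis",
             "high_gray_level_run_emphasis",
             "short_run_low_gray_level_emphasis",
             "short_run_high_gray_level_emphasis",
             "long_run_low_gray_level_emphasis",
             "long_run_high_gray_level_emphasis")
  glszm <- c("small_area_emphasis", "large_area_emphasis",
             "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
             "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
             "zone_percentage", "gray_level_variance", "zone_variance",
             "zone_entropy", "low_gray_level_zone_emphasis",
             "high_gray_level_zone_emphasis",
             "small_area_low_gray_level_emphasis",
             "small_area_high_gray_level_emphasis",
             "large_area_low_gray_level_emphasis",
             "large_area_high_gray_level_emphasis")
  gldm <- c("small_dependence_emphasis", "large_dependence_emphasis",
            "gray_level_nonuniformity", "dependence_nonuniformity",
            "dependence_nonuniformity_normalized", "gray_level_variance",
            "dependence_variance", "dependence_entropy",
            "low_gray_level_emphasis", "high_gray_level_emphasis",
            "small_dependence_low_gray_level_emphasis",
            "small_dependence_high_gray_level_emphasis",
            "large_dependence_low_gray_level_emphasis",
            "large_dependence_high_gray_level_emphasis")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  out <- rbind(
    data.frame(family = "firstorder", name = fo),
    data.frame(family = "glcm", name = glcm),
    data.frame(family = "glrlm", name = glrlm),
    data.frame(family = "glszm", name = glszm),
    data.frame(family = "gldm", name = gldm),
    data.frame(family = "ngtdm", name = ngtdm)
  )
  out$feature <- paste(out$family, out$name, sep = "_")
  stopifnot(nrow(out) == 92L, !anyDuplicated(out$feature))
  out
}

#' The 14-feature shape manifest
#'
#' 3D shape descriptors computed on the whole-tumor mask of the first
#' postcontrast DCE volume: mesh and voxel volume (mm^3), mesh surface area
#' (mm^2), surface-to-volume ratio, sphericity, two compactness variants,
#' spherical disproportion, maximum 3D diameter (mm), the three principal
#' axis lengths (mm), elongation and flatness.
#'
#' @return Character vector of the 14 shape feature names (frozen order).
#' @export
shape_feature_set <- function() {
  c("mesh_volume", "voxel_volume", "surface_area", "surface_volume_ratio",
    "sphericity", "compactness1", "compactness2", "spherical_disproportion",
    "maximum_3d_diameter", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness")
}

#' Sequential statistic sets per modality
#'
#' Ten trajectory statistics for DCE (six per-subject: mean, variance,
#' kurtosis, skewness, energy, entropy; four cohort-interactive:
#' Kendall-tau-b, conservation, stability, dispersion). DWI drops kurtosis
#' and entropy because three b-values are too few, leaving eight.
#'
#' @param axis_kind `"DCE_time"` or `"DWI_bvalue"`.
#' @return Character vector of statistic names.
#' @export
sequential_stat_set <- function(axis_kind = c("DCE_time", "DWI_bvalue")) {
  axis_kind <- match.arg(axis_kind)
  dce <- c("mean", "variance", "kurtosis", "skewness", "energy", "entropy",
           "kendall_tau_b", "conservation", "stability", "dispersion")
  if (axis_kind == "DCE_time") dce else setdiff(dce, c("kurtosis", "entropy"))
}
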