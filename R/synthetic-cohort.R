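#' Phantom specification for one subtype
#'
#' Parameters of the synthetic multiparametric phantom: an ellipsoidal
#' lesion on a noisy background, a class-specific Gaussian-random-field
#' texture inside the lesion, a piecewise-linear DCE enhancement trajectory
#' (wash-in to a peak phase, then washout) and mono-exponential DWI decay
#' with per-voxel ADC heterogeneity.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param spacing voxel spacing in mm.
#' @param semi_axes lesion ellipsoid semi-axes in mm.
#' @param background,background_noise_sd background signal level and
#'   Gaussian noise sd.
#' @param lesion_base pre-contrast lesion signal level.
#' @param texture_sigma Gaussian-random-field correlation length (voxels);
#'   the class's texture signature.
#' @param texture_amp additive texture amplitude inside the lesion (DCE).
#' @param dce_washin enhancement slope per phase up to the peak.
#' @param dce_peak_phase phase index (0..5) of peak enhancement.
#' @param dce_washout signal loss per phase after the peak.
#' @param dwi_s0 DWI signal at b = 0 inside the lesion.
#' @param adc_mean,adc_sd per-voxel apparent diffusion coefficient mean and
#'   heterogeneity sd, mm^2/s; ADC draws are truncated > 0.
#' @param dwi_texture_rel relative amplitude of the multiplicative texture
#'   field on the DWI S0 map.
#' @param background_adc background tissue ADC (mm^2/s).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         semi_axes = c(10, 8, 7),
                         background = 100, background_noise_sd = 5,
                         lesion_base = 120,
                         texture_sigma = 1.2, texture_amp = 12,
                         dce_washin = 45, dce_peak_phase = 4, dce_washout = 8,
                         dwi_s0 = 400, adc_mean = 1.0e-3, adc_sd = 1.5e-4,
                         dwi_texture_rel = 0.08, background_adc = 2.0e-3) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (adc_mean <= 0) stop("ADC mean must be positive")
  if (background_noise_sd < 0 || adc_sd < 0) stop("noise sds must be >= 0")
  if (any(2 * semi_axes >= grid_shape * spacing))
    stop("lesion larger than grid")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Default phantom specifications per IHC subtype
#'
#' The four defaults encode the qualitative radiology of the subtypes that
#' the analysis exploits: Luminal A enhances slowly and persistently with a
#' fine texture and high ADC; Luminal B is intermediate; HER2-positive
#' enhances fast with early washout; TN enhances briskly with marked
#' washout, the coarsest texture and the lowest, most heterogeneous ADC.
#'
#' @return Named list of [phantom_spec()] objects, one per subtype.
#' @export
default_phantom_specs <- function() {
  list(
    LuminalA = phantom_spec(texture_sigma = 0.8, dce_washin = 30,
                            dce_peak_phase = 5, dce_washout = 0,
                            adc_mean = 1.15e-3, adc_sd = 1.2e-4),
    LuminalB = phantom_spec(texture_sigma = 1.2, dce_washin = 45,
                            dce_peak_phase = 4, dce_washout = 8,
                            adc_mean = 1.00e-3, adc_sd = 1.5e-4),
    HER2pos  = phantom_spec(texture_sigma = 1.8, dce_washin = 65,
                            dce_peak_phase = 2, dce_washout = 15,
                            adc_mean = 0.90e-3, adc_sd = 2.0e-4),
    TN       = phantom_spec(texture_sigma = 2.6, dce_washin = 55,
                            dce_peak_phase = 3, dce_washout = 25,
                            adc_mean = 0.80e-3, adc_sd = 3.5e-4)
  )
}

# ellipsoidal mask centred on the grid
ellipsoid_mask <- function(grid_shape, spacing, semi_axes) {
  ctr <- (grid_shape - 1) / 2
  ax <- (seq_len(grid_shape[1]) - 1 - ctr[1]) * spacing[1] / semi_axes[1]
  ay <- (seq_len(grid_shape[2]) - 1 - ctr[2]) * spacing[2] / semi_axes[2]
  az <- (seq_len(grid_shape[3]) - 1 - ctr[3]) * spacing[3] / semi_axes[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  r2 <= 1
}

# zero-mean, unit-variance Gaussian random field with correlation length
# `sigma` voxels (FFT convolution of white noise with a periodic Gaussian)
gaussian_random_field <- function(grid_shape, sigma) {
  noise <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (sigma <= 0) return(noise)
  kern1 <- function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
    stats::dnorm(d, 0, sigma)
  }
  k <- outer(outer(kern1(grid_shape[1]), kern1(grid_shape[2])),
             kern1(grid_shape[3]))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    prod(grid_shape)
  s <- stats::sd(sm)
  if (s > 0) sm / s else sm
}

#' Generate one synthetic phantom subject
#'
#' Builds a 6-phase DCE series whose mean lesion intensity follows the
#' class's piecewise-linear enhancement curve, and a 3-b-value DWI series
#' where the lesion signal decays as `S0 * exp(-b * ADC)` voxelwise with
#' per-voxel ADC drawn from a truncated normal. The same ellipsoidal mask
#' (grid-centred) is returned per modality. Identical seeds give
#' bit-identical subjects.
#'
#' @param spec a [phantom_spec()].
#' @param label subtype label, one of [subtype_levels()].
#' @param seed integer seed.
#' @param id subject id.
#' @param b_values DWI b-values (s/mm^2).
#' @return An [mr_subject()].
#' @export
generate_phantom_subject <- function(spec, label, seed, id = "phantom",
                                     b_values = c(50, 400, 800)) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  gs <- spec$grid_shape
  mask <- ellipsoid_mask(gs, spec$spacing, spec$semi_axes)
  tex <- gaussian_random_field(gs, spec$texture_sigma)

  enh <- function(p) {
    if (p <= spec$dce_peak_phase) spec$dce_washin * p
    else spec$dce_washin * spec$dce_peak_phase -
      spec$dce_washout * (p - spec$dce_peak_phase)
  }
  dce_vols <- lapply(0:5, function(p) {
    v <- array(spec$background, dim = gs)
    if (spec$background_noise_sd > 0)
      v <- v + array(stats::rnorm(prod(gs), 0, spec$background_noise_sd), gs)
    v[mask] <- spec$lesion_base + enh(p) + spec$texture_amp * tex[mask] +
      if (spec$background_noise_sd > 0)
        stats::rnorm(sum(mask), 0, spec$background_noise_sd) else 0
    image_volume(v, spec$spacing, axis_label = paste0("DCE_phase", p))
  })

  # per-voxel ADC, truncated positive
  adc <- array(spec$background_adc, dim = gs)
  adc_les <- stats::rnorm(sum(mask), spec$adc_mean, spec$adc_sd)
  while (any(adc_les <= 0))
    adc_les[adc_les <= 0] <- stats::rnorm(sum(adc_les <= 0),
                                          spec$adc_mean, spec$adc_sd)
  adc[mask] <- adc_les
  s0 <- array(spec$background * 0.6, dim = gs)
  s0[mask] <- spec$dwi_s0 * (1 + spec$dwi_texture_rel * tex[mask])
  dwi_vols <- lapply(b_values, function(b) {
    v <- s0 * exp(-b * adc)
    if (spec$background_noise_sd > 0)
      v <- v + array(stats::rnorm(prod(gs), 0, spec$background_noise_sd), gs)
    image_volume(v, spec$spacing, axis_label = paste0("DWI_b", b))
  })

  m <- tumor_mask(mask, spec$spacing)
  mr_subject(id,
             image_series(dce_vols, "DCE_time", 0:5),
             image_series(dwi_vols, "DWI_bvalue", b_values),
             m, m, label)
}

#' Cohort specification
#'
#' @param n_per_class named integer counts for the four subtypes; the
#'   default reproduces the study prevalence 26/68/18/22.
#' @param phantom_specs named list of [phantom_spec()] per subtype.
#' @param seed integer cohort seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(LuminalA = 26L, LuminalB = 68L,
                                        HER2pos = 18L, TN = 22L),
                        phantom_specs = default_phantom_specs(),
                        seed = 1L) {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% subtype_levels()))
    stop("`n_per_class` must be named with subtype levels")
  if (any(n_per_class < 0)) stop("class counts must be >= 0")
  if (sum(n_per_class > 0) < 2)
    stop("at least two classes must be non-empty")
  structure(list(n_per_class = n_per_class, phantom_specs = phantom_specs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a phantom image cohort
#'
#' @param spec a [cohort_spec()].
#' @return List of [mr_subject()]s, in class-block order; per-subject seeds
#'   are drawn deterministically from the cohort seed so cohorts are
#'   reproducible and subjects independent.
#' @export
generate_image_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- sum(spec$n_per_class)
  if (n_tot == 0) stop("empty cohort")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  labels <- rep(names(spec$n_per_class), spec$n_per_class)
  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    out[[i]] <- generate_phantom_subject(
      spec$phantom_specs[[labels[i]]], labels[i], subj_seeds[i],
      id = sprintf("S%03d", i))
  }
  out
}

#' Specification of a directly generated feature table
#'
#' Generates subjects-by-features matrices with planted structure for
#' testing the selection and classification stages without image
#' extraction: `n_informative` columns carry a standardized between-class
#' mean separation of `effect_size`; `n_correlated_blocks` blocks of noise
#' columns share a latent factor giving pairwise correlation
#' `block_correlation`; everything else is iid standard normal.
#'
#' @param n_subjects,n_features table dimensions.
#' @param n_informative number of planted informative columns; their
#'   class-mean patterns are mutually spread (pairwise pattern correlation
#'   at most 0.8) so the planted set is not internally redundant.
#' @param effect_size standardized sd of the class-mean pattern of each
#'   informative column (prevalence-weighted).
#' @param n_correlated_blocks,block_size,block_correlation correlated-noise
#'   block layout; |correlation| < 1.
#' @param prevalences named class proportions (default: study prevalence).
#' @param seed integer seed.
#' @return An object of class `table_spec`.
#' @export
table_spec <- function(n_subjects = 134L, n_features = 500L,
                       n_informative = 10L, effect_size = 0.8,
                       n_correlated_blocks = 0L, block_size = 4L,
                       block_correlation = 0.8,
                       prevalences = c(LuminalA = 26, LuminalB = 68,
                                       HER2pos = 18, TN = 22) / 134,
                       seed = 1L) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  if (abs(block_correlation) >= 1) stop("|block_correlation| must be < 1")
  if (n_informative + n_correlated_blocks * block_size > n_features)
    stop("correlated blocks overlap informative columns")
  structure(as.list(environment()), class = "table_spec")
}

#' Generate a feature table with planted structure
#'
#' @param spec a [table_spec()].
#' @return A [feature_table()]; column meta uses `group` to mark
#'   `"informative"`, `"block"` (with the block id in `base_feature`) and
#'   `"noise"` columns.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_subjects; p <- spec$n_features
  classes <- names(spec$prevalences)
  counts <- floor(spec$prevalences * n)
  rem <- n - sum(counts)
  if (rem > 0) {  # largest remainders get the leftover subjects
    frac <- spec$prevalences * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  labels <- sample(rep(classes, counts))
  y <- factor(labels, levels = classes)

  X <- matrix(stats::rnorm(n * p), n, p)
  group <- rep("noise", p)
  base <- rep("", p)

  k <- length(classes)
  w <- as.vector(table(y)) / n  # realized class prevalences
  # class-mean patterns are standardized under the prevalence weights and
  # spread so that pairwise pattern correlation stays <= 0.8: with a unit
  # within-class sd the marginal between-feature correlation is then
  # effect^2 / (1 + effect^2) * 0.8, below the 0.4 pruning threshold, so
  # the planted set is jointly recoverable (not internally redundant)
  accepted <- list()
  draw_contrast <- function() {
    best <- NULL; best_cor <- Inf
    for (try in 1:300) {
      cm <- stats::rnorm(k)
      mu_w <- sum(w * cm)
      sd_w <- sqrt(sum(w * (cm - mu_w)^2))
      if (sd_w == 0) next
      cm <- (cm - mu_w) / sd_w
      mc <- if (length(accepted))
        max(abs(vapply(accepted, function(a) sum(w * a * cm), 0))) else 0
      if (mc <= 0.8) return(cm)
      if (mc < best_cor) { best <- cm; best_cor <- mc }
    }
    best
  }
  for (j in seq_len(spec$n_informative)) {
    if (spec$effect_size == 0) { group[j] <- "informative"; next }
    cm <- draw_contrast()
    accepted[[length(accepted) + 1]] <- cm
    X[, j] <- X[, j] + spec$effect_size * cm[as.integer(y)]
    group[j] <- "informative"
  }
  if (spec$n_correlated_blocks > 0) {
    rho <- spec$block_correlation
    col0 <- spec$n_informative
    for (b in seq_len(spec$n_correlated_blocks)) {
      z <- stats::rnorm(n)
      cols <- col0 + (b - 1) * spec$block_size + seq_len(spec$block_size)
      X[, cols] <- sqrt(abs(rho)) * z * sign(rho)^0 +
        sqrt(1 - abs(rho)) * X[, cols]
      group[cols] <- "block"
      base[cols] <- sprintf("block%02d", b)
    }
  }
  meta <- new_feature_meta(sprintf("f%04d", seq_len(p)), group, "synthetic",
                           base, "")
  feature_table(X, sprintf("S%03d", seq_len(n)), as.character(y), meta)
}
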