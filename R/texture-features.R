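#' Discretize ROI intensities to a fixed bin count
#'
#' Fixed-bin-count discretization inside the mask: the ROI intensity range
#' is split into `n_bins` equal-width bins, making every downstream texture
#' feature invariant to affine rescaling of the ROI intensities. A constant
#' ROI maps to a single gray level.
#'
#' @param values numeric vector of ROI voxel intensities.
#' @param n_bins number of gray levels.
#' @return Integer vector of gray levels in 1..`n_bins`.
#' @export
discretize_roi <- function(values, n_bins = 32L) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  g <- floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(g, as.integer(n_bins))
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

first_order_features <- function(vals, voxel_volume, n_bins) {
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  m3 <- mean((vals - mu)^3)
  m4 <- mean((vals - mu)^4)
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  inner <- vals[vals >= qs[1] & vals <= qs[4]]
  p <- tabulate(discretize_roi(vals, n_bins), n_bins) / n
  c(energy = sum(vals^2),
    total_energy = voxel_volume * sum(vals^2),
    entropy = -sum(xlog2(p)),
    minimum = min(vals),
    percentile10 = qs[1],
    percentile90 = qs[4],
    maximum = max(vals),
    mean = mu,
    median = stats::median(vals),
    interquartile_range = qs[3] - qs[2],
    range = max(vals) - min(vals),
    mean_absolute_deviation = mean(abs(vals - mu)),
    robust_mad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    root_mean_squared = sqrt(mean(vals^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

glcm_features <- function(counts, ng) {
  # counts: ng*ng x 13 per-direction symmetric counts; accumulate over
  # directions, then normalize once
  P <- matrix(rowSums(counts), ng, ng)
  tot <- sum(P)
  if (tot == 0) P[1, 1] <- tot <- 1  # single isolated voxel: degenerate
  P <- P / tot
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)                      # symmetric: mu_x = mu_y
  sx <- sqrt(sum((i - mu)^2 * P))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)
  hx <- -sum(xlog2(px))
  hxy <- -sum(xlog2(P))
  pipj <- outer(px, px)
  hxy1 <- -sum(P * ifelse(pipj > 0, log2(pipj), 0))
  hxy2 <- -sum(xlog2(pipj))
  imc2sq <- 1 - exp(-2 * (hxy2 - hxy))
  c(autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sx > 0) (sum(i * j * P) - mu^2) / sx^2 else 0,
    difference_average = da,
    difference_entropy = -sum(xlog2(p_diff)),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    id = sum(P / (1 + abs(i - j))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    imc1 = if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0,
    imc2 = if (imc2sq > 0) sqrt(imc2sq) else 0,
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    maximum_probability = max(P),
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(xlog2(p_sum)),
    sum_of_squares = sum((i - mu)^2 * P))
}

# shared formulas for run-length (j = run length) and size-zone
# (j = zone size) matrices; R holds counts, n_voxels the ROI size
rl_sz_features <- function(R, n_voxels, names_out) {
  ng <- nrow(R)
  nr <- sum(R)
  if (nr == 0) { out <- rep(0, 16); names(out) <- names_out; return(out) }
  i <- row(R); j <- col(R)
  p <- R / nr
  mu_g <- sum(i * p); mu_j <- sum(j * p)
  out <- c(sum(R / j^2) / nr,                       # short emphasis
           sum(R * j^2) / nr,                       # long emphasis
           sum(rowSums(R)^2) / nr,                  # gray-level NU
           sum(rowSums(R)^2) / nr^2,                # gray-level NU normalized
           sum(colSums(R)^2) / nr,                  # length/size NU
           sum(colSums(R)^2) / nr^2,                # ... normalized
           nr / n_voxels,                           # run/zone percentage
           sum((i - mu_g)^2 * p),                   # gray-level variance
           sum((j - mu_j)^2 * p),                   # run/zone variance
           -sum(xlog2(p)),                          # entropy
           sum(R / i^2) / nr,                       # low gray-level emphasis
           sum(R * i^2) / nr,                       # high gray-level emphasis
           sum(R / (i^2 * j^2)) / nr,               # short+low
           sum(R * i^2 / j^2) / nr,                 # short+high
           sum(R * j^2 / i^2) / nr,                 # long+low
           sum(R * i^2 * j^2) / nr)                 # long+high
  names(out) <- names_out
  out
}

gldm_features <- function(D) {
  ng <- nrow(D)
  nz <- sum(D)
  nms <- texture_feature_set()
  nms <- nms$name[nms$family == "gldm"]
  if (nz == 0) { out <- rep(0, 14); names(out) <- nms; return(out) }
  i <- row(D); j <- col(D)   # j = dependence count + 1, so j >= 1
  p <- D / nz
  mu_g <- sum(i * p); mu_j <- sum(j * p)
  out <- c(sum(D / j^2) / nz,
           sum(D * j^2) / nz,
           sum(rowSums(D)^2) / nz,
           sum(colSums(D)^2) / nz,
           sum(colSums(D)^2) / nz^2,
           sum((i - mu_g)^2 * p),
           sum((j - mu_j)^2 * p),
           -sum(xlog2(p)),
           sum(D / i^2) / nz,
           sum(D * i^2) / nz,
           sum(D / (i^2 * j^2)) / nz,
           sum(D * i^2 / j^2) / nz,
           sum(D * j^2 / i^2) / nz,
           sum(D * i^2 * j^2) / nz)
  names(out) <- nms
  out
}

ngtdm_features <- function(M) {
  ng <- nrow(M)
  n_i <- M[, 1]; s_i <- M[, 2]
  np <- sum(n_i)
  nms <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  if (np == 0) { out <- rep(0, 5); names(out) <- nms; return(out) }
  p_i <- n_i / np
  lev <- seq_len(ng)
  act <- which(p_i > 0)
  ngp <- length(act)
  co_den <- sum(p_i * s_i)
  coarseness <- if (co_den > 0) min(1 / co_den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i[act], p_i[act]) * outer(lev[act], lev[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_i) / np
  } else 0
  # double sums below run over ordered pairs (i, j) of occupied levels
  bus_den <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], `-`)))
  busyness <- if (bus_den > 0) sum(p_i * s_i) / bus_den else 0
  complexity <- if (ngp > 0) {
    pi_a <- p_i[act]; si_a <- s_i[act]; li <- lev[act]
    sum(abs(outer(li, li, `-`)) *
          outer(pi_a * si_a, pi_a * si_a, `+`) /
          outer(pi_a, pi_a, `+`)) / np
  } else 0
  s_tot <- sum(s_i)
  strength <- if (s_tot > 0 && ngp > 1)
    sum(outer(p_i[act], p_i[act], `+`) * outer(lev[act], lev[act], `-`)^2) / s_tot
  else 0
  out <- c(coarseness, contrast, busyness, complexity, strength)
  names(out) <- nms
  out
}

#' Compute the 92 texture features of a masked volume
#'
#' First-order statistics are computed on raw ROI intensities (histogram
#' statistics on the discretized levels); GLCM counts are accumulated
#' symmetrically over the 13 unique 3D directions at distance 1 and then
#' normalized; GLRLM counts are accumulated over the same 13 directions;
#' GLSZM zones use 26-connectivity; GLDM uses the 26-neighbourhood with
#' dependence tolerance 0; NGTDM uses the 26-neighbourhood mean. Any value
#' whose defining denominator vanishes on a degenerate ROI is returned as 0,
#' so all 92 values are finite.
#'
#' @param volume an [image_volume()].
#' @param mask a [tumor_mask()] on the same grid.
#' @param n_bins fixed gray-level bin count.
#' @return Named numeric vector of length 92 in [texture_feature_set()]
#'   order (names `family_name`).
#' @export
compute_texture_features <- function(volume, mask, n_bins = 32L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "tumor_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("mask grid does not match volume grid")
  mvox <- mask$voxels
  if (!any(mvox)) stop("empty mask")

  # crop to the mask bounding box; voxels outside the mask never contribute
  idx <- which(mvox, arr.ind = TRUE)
  rg <- apply(idx, 2, range)
  sub <- function(a) a[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2],
                       rg[1, 3]:rg[2, 3], drop = FALSE]
  m <- sub(mvox); v <- sub(volume$voxels)
  vals <- v[m]
  disc <- array(0L, dim = dim(m))
  disc[m] <- discretize_roi(vals, n_bins)
  ng <- as.integer(n_bins)
  dm <- as.integer(dim(m))

  ts <- texture_feature_set()
  fo <- first_order_features(vals, prod(volume$spacing), n_bins)
  glcm <- glcm_features(cpp_glcm(as.integer(disc), dm, ng), ng)
  rl_list <- cpp_glrlm(as.integer(disc), dm, ng)
  maxlen <- max(vapply(rl_list, ncol, 0L))
  Rm <- matrix(0, ng, maxlen)
  for (d in rl_list) Rm[, seq_len(ncol(d))] <- Rm[, seq_len(ncol(d))] + d
  Rm <- Rm / length(rl_list)
  glrlm <- rl_sz_features(Rm, length(vals), ts$name[ts$family == "glrlm"])
  glszm <- rl_sz_features(cpp_glszm(as.integer(disc), dm, ng), length(vals),
                          ts$name[ts$family == "glszm"])
  gldm <- gldm_features(cpp_gldm(as.integer(disc), dm, ng))
  ngtdm <- ngtdm_features(cpp_ngtdm(as.integer(disc), dm, ng))

  out <- c(fo, glcm, glrlm, glszm, gldm, ngtdm)
  names(out) <- ts$feature
  out[!is.finite(out)] <- 0
  out
}
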