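#' Per-subject trajectory statistics
#'
#' Descriptive statistics of one subject's feature trajectory across the
#' acquisition axis (6 DCE phases or 3 DWI b-values). Moments are population
#' (1/T) moments — the trajectory is a fixed short sequence, not a sample.
#' Energy is the raw sum of squares; entropy is Shannon entropy (bits) of
#' the |x|-normalized mass. Statistics whose defining denominator vanishes
#' (skewness/kurtosis of a constant trajectory, entropy of an all-zero one)
#' return 0.
#'
#' @param x numeric trajectory, length >= 2.
#' @param which statistics to compute; kurtosis and entropy require
#'   length >= 4 (they are dropped for 3-point DWI trajectories).
#' @return Named numeric vector.
#' @export
per_subject_stats <- function(x, which = c("mean", "variance", "kurtosis",
                                           "skewness", "energy", "entropy")) {
  if (length(x) < 2) stop("trajectory must have length >= 2")
  if (any(c("kurtosis", "entropy") %in% which) && length(x) < 4)
    stop("kurtosis and entropy require a trajectory of length >= 4")
  t_len <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  out <- c()
  for (w in which) {
    out[[w]] <- switch(
      w,
      mean = mu,
      variance = m2,
      kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
      skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
      energy = sum(x^2),
      entropy = {
        s <- sum(abs(x))
        if (s > 0) { p <- abs(x) / s; -sum(xlog2(p)) } else 0
      },
      stop("unknown statistic: ", w)
    )
  }
  unlist(out)
}

#' Kendall tau-b rank correlation with tie correction
#'
#' `tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2))` where C/D count concordant
#' and discordant pairs, `n0 = T(T-1)/2`, and `n1`, `n2` correct for ties in
#' each argument. Returns 0 when either denominator factor is 0 (a constant
#' argument).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 2) stop("need length >= 2")
  pr <- utils::combn(n, 2)
  sx <- sign(x[pr[1, ]] - x[pr[2, ]])
  sy <- sign(y[pr[1, ]] - y[pr[2, ]])
  num <- sum(sx * sy)
  d1 <- sum(sx != 0)
  d2 <- sum(sy != 0)
  if (d1 == 0 || d2 == 0) return(0)
  num / sqrt(d1 * d2)
}

# min-max normalization of each row; constant rows map to all-zero
minmax_rows <- function(M) {
  rng <- apply(M, 1, range)
  span <- rng[2, ] - rng[1, ]
  out <- (M - rng[1, ]) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  out
}

#' Cohort-interactive trajectory statistics
#'
#' Statistics of subject `i`'s trajectory relative to the rest of the
#' cohort, for one base feature:
#' \describe{
#'   \item{kendall_tau_b}{mean pairwise tau-b between subject i and every
#'     other subject — the "dependence emphasis" of the trajectory shape.}
#'   \item{conservation}{mean over other subjects of the fraction of the
#'     T-1 successive steps whose difference signs agree.}
#'   \item{stability}{`1 / (1 + RMSD)` between subject i's min-max
#'     normalized trajectory and the mean normalized trajectory of the
#'     others.}
#'   \item{dispersion}{root mean square of subject i's per-time-point
#'     cohort z-scores (population sd over the full cohort; 0 where the sd
#'     is 0).}
#' }
#'
#' @param M numeric N x T trajectory matrix (one row per subject), N >= 2.
#' @param i subject row index.
#' @return Named numeric vector of the four statistics.
#' @export
cohort_interactive_stats <- function(M, i) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("cohort-interactive statistics require N >= 2")
  all <- cohort_interactive_all(M)
  c(kendall_tau_b = all$kendall_tau_b[i],
    conservation = all$conservation[i],
    stability = all$stability[i],
    dispersion = all$dispersion[i])
}

# vectorized computation of the four interactive statistics for all subjects
cohort_interactive_all <- function(M) {
  n <- nrow(M); t_len <- ncol(M)
  pr <- utils::combn(t_len, 2)
  # sign of each time-point pair difference, per subject: concordant minus
  # discordant counts between subjects are then the Gram matrix S %*% t(S)
  S <- sign(M[, pr[1, ], drop = FALSE] - M[, pr[2, ], drop = FALSE])
  num <- S %*% t(S)
  nz <- sqrt(rowSums(S != 0))
  den <- outer(nz, nz)
  tau <- ifelse(den > 0, num / den, 0)
  diag(tau) <- 0
  tau_i <- rowSums(tau) / (n - 1)

  # step-sign agreement
  D <- sign(M[, -1, drop = FALSE] - M[, -t_len, drop = FALSE])
  agree <- matrix(0, n, n)
  for (s in seq_len(t_len - 1))
    agree <- agree + outer(D[, s], D[, s], `==`)
  agree <- agree / (t_len - 1)
  diag(agree) <- 0
  conservation <- rowSums(agree) / (n - 1)

  # stability against the others' mean normalized trajectory
  Xn <- minmax_rows(M)
  cs <- colSums(Xn)
  others_mean <- (matrix(cs, n, t_len, byrow = TRUE) - Xn) / (n - 1)
  rmsd <- sqrt(rowMeans((Xn - others_mean)^2))
  stability <- 1 / (1 + rmsd)

  # z-score dispersion over the full cohort (population sd)
  mu <- colMeans(M)
  sdev <- sqrt(pmax(colMeans(M^2) - mu^2, 0))
  Z <- sweep(M, 2, mu)
  Z <- sweep(Z, 2, ifelse(sdev > 0, sdev, 1), `/`)
  Z[, sdev == 0] <- 0
  dispersion <- sqrt(rowMeans(Z^2))

  list(kendall_tau_b = tau_i, conservation = conservation,
       stability = stability, dispersion = dispersion)
}
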