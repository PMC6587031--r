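# independent brute-force oracles shared by the unit and acceptance tests;
# deliberately written as plain loops with no code shared with the package

# pair-enumeration Kendall tau-b with explicit tie counting
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- txy <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) txy <- txy + 1
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  n1 <- tx + txy  # pairs tied in x
  n2 <- ty + txy  # pairs tied in y
  if (n0 - n1 == 0 || n0 - n2 == 0) return(0)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# loop-based cohort-interactive statistics for subject i
oracle_interactive <- function(M, i) {
  n <- nrow(M)
  others <- setdiff(seq_len(n), i)
  taus <- vapply(others, function(j) oracle_tau_b(M[i, ], M[j, ]), 0)
  cons <- vapply(others, function(j) {
    mean(sign(diff(M[i, ])) == sign(diff(M[j, ])))
  }, 0)
  norm1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  xi <- norm1(M[i, ])
  cbar <- colMeans(do.call(rbind, lapply(others, function(j) norm1(M[j, ]))))
  stab <- 1 / (1 + sqrt(mean((xi - cbar)^2)))
  mu <- colMeans(M)
  sdev <- sqrt(colMeans(sweep(M, 2, mu)^2))
  z <- (M[i, ] - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0] <- 0
  c(kendall_tau_b = mean(taus), conservation = mean(cons),
    stability = stab, dispersion = sqrt(mean(z^2)))
}

# greedy correlation-pruning scan
oracle_prune <- function(X, ids, thr, k) {
  kept <- character(0)
  for (id in ids) {
    if (length(kept) == k) break
    ok <- TRUE
    for (j in kept)
      if (abs(stats::cor(X[, id], X[, j])) > thr) { ok <- FALSE; break }
    if (ok) kept <- c(kept, id)
  }
  kept
}

# brute-force symmetric co-occurrence counts over the 13 unique directions
oracle_glcm_counts <- function(disc, ng) {
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
                c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
                c(1,-1,1), c(1,-1,-1))
  dm <- dim(disc)
  P <- matrix(0, ng, ng)
  for (d in seq_len(nrow(dirs))) {
    off <- dirs[d, ]
    for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
      g1 <- disc[x, y, z]
      if (g1 == 0) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || y2 < 1 || z2 < 1 || x2 > dm[1] || y2 > dm[2] || z2 > dm[3])
        next
      g2 <- disc[x2, y2, z2]
      if (g2 == 0) next
      P[g1, g2] <- P[g1, g2] + 1
      P[g2, g1] <- P[g2, g1] + 1
    }
  }
  P
}
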