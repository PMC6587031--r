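test_that("per-subject trajectory statistics match direct arithmetic", {
  s <- per_subject_stats(c(2, 2, 2), which = c("mean", "variance",
                                               "skewness", "energy"))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["variance"]], 0)
  expect_equal(s[["skewness"]], 0)
  expect_equal(s[["energy"]], 12)
  expect_equal(per_subject_stats(c(2, 2, 2, 2))[["kurtosis"]], 0)

  s2 <- per_subject_stats(c(1, 2, 3), which = c("mean", "variance",
                                                "skewness", "energy"))
  expect_equal(s2[["mean"]], 2)
  expect_equal(s2[["variance"]], 2 / 3)
  expect_equal(s2[["skewness"]], 0)
  expect_equal(s2[["energy"]], 14)

  x <- c(1, 2, 4, 8, 16, 32)
  s3 <- per_subject_stats(x)
  expect_equal(s3[["mean"]], 10.5)
  expect_equal(s3[["energy"]], 1365)
  # population variance: sum of squared deviations from 10.5 is 703.5
  expect_equal(s3[["variance"]], 703.5 / 6, tolerance = 1e-12)
  # entropy oracle: |x|-normalized Shannon entropy in bits
  p <- abs(x) / sum(abs(x))
  expect_equal(s3[["entropy"]], -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(per_subject_stats(c(0, 0, 0, 0))[["entropy"]], 0)

  expect_error(per_subject_stats(c(1)), ">= 2")
  expect_error(per_subject_stats(c(1, 2, 3), which = "kurtosis"), ">= 4")
  expect_error(per_subject_stats(c(1, 2), which = "median"), "unknown")
})

test_that("kendall tau-b handles ties and matches oracles", {
  expect_equal(kendall_tau_b(1:3, 4:6), 1)
  expect_equal(kendall_tau_b(1:3, 3:1), -1)
  expect_equal(kendall_tau_b(c(1, 2, 2), c(1, 2, 3)), 2 / sqrt(6),
               tolerance = 1e-12)
  expect_equal(kendall_tau_b(c(5, 5, 5), c(1, 2, 3)), 0)  # degenerate
  expect_error(kendall_tau_b(1:3, 1:4), "mismatch")

  set.seed(12)
  for (rep in 1:20) {
    x <- sample(1:4, 6, replace = TRUE)
    y <- rnorm(6)
    expect_equal(kendall_tau_b(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
    if (length(unique(x)) > 1)  # stats::cor agrees where it is defined
      expect_equal(kendall_tau_b(x, y),
                   suppressWarnings(cor(x, y, method = "kendall")),
                   tolerance = 1e-12)
    # symmetry and self-correlation
    expect_equal(kendall_tau_b(x, y), kendall_tau_b(y, x), tolerance = 1e-12)
    if (length(unique(x)) > 1) expect_equal(kendall_tau_b(x, x), 1)
  }
})

test_that("cohort-interactive statistics match a brute-force oracle", {
  set.seed(33)
  M <- matrix(rnorm(5 * 6), 5, 6)
  M[2, 3] <- M[2, 2]  # inject a tie
  for (i in 1:5)
    expect_equal(cohort_interactive_stats(M, i), oracle_interactive(M, i),
                 tolerance = 1e-12)

  # all strictly increasing: full concordance
  Minc <- t(replicate(3, cumsum(runif(6, 0.1, 1))))
  for (i in 1:3) {
    st <- cohort_interactive_stats(Minc, i)
    expect_equal(st[["kendall_tau_b"]], 1)
    expect_equal(st[["conservation"]], 1)
  }

  # a subject sitting exactly at the per-time-point mean has dispersion 0
  M2 <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  expect_equal(cohort_interactive_stats(M2, 3)[["dispersion"]], 0)
  expect_error(cohort_interactive_stats(M[1, , drop = FALSE], 1), "N >= 2")
})

test_that("interactive statistics obey their symmetry and scale invariances", {
  set.seed(44)
  M <- matrix(rnorm(6 * 6), 6, 6)
  base <- cohort_interactive_stats(M, 1)
  # permuting the other subjects leaves subject 1's statistics unchanged
  Mp <- M[c(1, 5, 3, 6, 2, 4), ]
  expect_equal(cohort_interactive_stats(Mp, 1), base, tolerance = 1e-12)
  # a common positive rescaling leaves tau-b and conservation unchanged
  sc <- cohort_interactive_stats(3.2 * M, 1)
  expect_equal(sc[["kendall_tau_b"]], base[["kendall_tau_b"]], tolerance = 1e-12)
  expect_equal(sc[["conservation"]], base[["conservation"]], tolerance = 1e-12)
  # z-score identity: mean square of dispersion over the cohort is 1 per
  # time point, i.e. mean_i dispersion_i^2 = 1 when all sds are nonzero
  disp <- vapply(1:6, function(i) cohort_interactive_stats(M, i)[["dispersion"]], 0)
  expect_equal(mean(disp^2), 1, tolerance = 1e-12)
})
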