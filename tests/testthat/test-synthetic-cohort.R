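test_that("phantom generation is deterministic under a fixed seed", {
  sp <- tiny_phantom_specs()$TN
  s1 <- generate_phantom_subject(sp, "TN", 99)
  s2 <- generate_phantom_subject(sp, "TN", 99)
  expect_identical(s1$dce$volumes[[4]]$voxels, s2$dce$volumes[[4]]$voxels)
  expect_identical(s1$dwi$volumes[[3]]$voxels, s2$dwi$volumes[[3]]$voxels)
  s3 <- generate_phantom_subject(sp, "TN", 100)
  expect_false(identical(s1$dce$volumes[[1]]$voxels, s3$dce$volumes[[1]]$voxels))
})

test_that("noise-free DWI follows the mono-exponential closed form", {
  sp <- tiny_phantom_specs()$LuminalB
  sp$background_noise_sd <- 0; sp$adc_sd <- 0; sp$dwi_texture_rel <- 0
  s <- generate_phantom_subject(sp, "LuminalB", 5)
  m <- s$dwi_mask$voxels
  means <- vapply(s$dwi$volumes, function(v) mean(v$voxels[m]), 0)
  expect_equal(means[3], sp$dwi_s0 * exp(-800 * sp$adc_mean), tolerance = 1e-12)
  # log lesion mean is linear in b with slope -ADC
  slope <- stats::coef(stats::lm(log(means) ~ s$dwi$axis_values))[2]
  expect_equal(unname(slope), -sp$adc_mean, tolerance = 1e-6)
  # multiplicative S0 texture preserves the log-linearity exactly
  sp$dwi_texture_rel <- 0.1
  s2 <- generate_phantom_subject(sp, "LuminalB", 5)
  means2 <- vapply(s2$dwi$volumes, function(v) mean(v$voxels[m]), 0)
  slope2 <- stats::coef(stats::lm(log(means2) ~ s2$dwi$axis_values))[2]
  expect_equal(unname(slope2), -sp$adc_mean, tolerance = 1e-6)
})

test_that("DCE wash-in slope monotonically drives early enhancement", {
  sp <- tiny_phantom_specs()$LuminalA
  sp$background_noise_sd <- 0; sp$texture_amp <- 0
  deltas <- vapply(c(10, 30, 60), function(w) {
    sp$dce_washin <- w
    s <- generate_phantom_subject(sp, "LuminalA", 3)
    m <- s$dce_mask$voxels
    mean(s$dce$volumes[[2]]$voxels[m]) - mean(s$dce$volumes[[1]]$voxels[m])
  }, 0)
  expect_true(all(diff(deltas) > 0))
  expect_equal(deltas, c(10, 30, 60), tolerance = 1e-9)
})

test_that("ellipsoid mask voxel count matches the continuous volume", {
  sp <- phantom_spec(grid_shape = c(20L, 20L, 20L), semi_axes = c(6, 6, 6))
  s <- generate_phantom_subject(sp, "TN", 1)
  n_vox <- sum(s$dce_mask$voxels)
  expect_lt(abs(n_vox - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.05)
})

test_that("image cohorts honour class counts and the cohort seed", {
  cs <- cohort_spec(c(LuminalA = 2L, LuminalB = 2L, HER2pos = 0L, TN = 0L),
                    tiny_phantom_specs(), seed = 21)
  coh <- generate_image_cohort(cs)
  expect_length(coh, 4)
  expect_identical(vapply(coh, function(s) s$label, ""),
                   c("LuminalA", "LuminalA", "LuminalB", "LuminalB"))
  coh2 <- generate_image_cohort(cs)
  expect_identical(coh[[2]]$dce$volumes[[1]]$voxels,
                   coh2[[2]]$dce$volumes[[1]]$voxels)
  # default prevalence reproduces the 134-subject cohort structure
  expect_identical(sum(cohort_spec()$n_per_class), 134L)
  expect_error(cohort_spec(c(LuminalA = 1L, LuminalB = 0L, HER2pos = 0L,
                             TN = 0L)), "two classes")
})

test_that("generated feature tables carry the planted structure", {
  # same seed -> identical table
  ts <- table_spec(n_subjects = 60, n_features = 40, n_informative = 5,
                   seed = 2)
  expect_identical(generate_feature_table(ts)$values,
                   generate_feature_table(ts)$values)

  # a 0.99-correlated block of 2 shows sample r > 0.9 at n = 200
  tb <- generate_feature_table(table_spec(
    n_subjects = 200, n_features = 10, n_informative = 0,
    n_correlated_blocks = 1, block_size = 2, block_correlation = 0.99,
    seed = 7))
  blk <- tb$meta$name[tb$meta$group == "block"]
  expect_gt(stats::cor(tb$values[, blk[1]], tb$values[, blk[2]]), 0.9)

  # zero effect size: per-column ANOVA rejects at about the nominal rate
  rej <- unlist(lapply(1:6, function(s) {
    tb0 <- generate_feature_table(table_spec(
      n_subjects = 134, n_features = 400, n_informative = 400,
      effect_size = 0, seed = s))
    p <- apply(tb0$values, 2, per_feature_pvalue, labels = tb0$labels,
               task = "four_class")
    p < 0.05
  }))
  rate <- mean(rej)  # 2,400 null columns
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)

  # informative columns separate classes at the configured effect size
  tb1 <- generate_feature_table(table_spec(
    n_subjects = 134, n_features = 20, n_informative = 10,
    effect_size = 1, seed = 3))
  p_inf <- apply(tb1$values[, 1:10], 2, per_feature_pvalue,
                 labels = tb1$labels, task = "four_class")
  expect_true(all(p_inf < 0.01))
})
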