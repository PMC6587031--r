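test_that("per-feature p-values agree with stats::aov and stats::t.test", {
  set.seed(60)
  y4 <- factor(rep(c("LuminalA", "LuminalB", "HER2pos", "TN"), c(8, 17, 5, 6)))
  for (rep in 1:5) {
    x <- rnorm(length(y4)) + as.integer(y4) * runif(1, 0, 0.6)
    p <- per_feature_pvalue(x, y4, "four_class")
    p_ref <- summary(stats::aov(x ~ y4))[[1]]$`Pr(>F)`[1]
    expect_equal(p, p_ref, tolerance = 1e-10)
  }
  y2 <- factor(rep(c("nonTN", "TN"), c(24, 12)))
  for (rep in 1:5) {
    x <- rnorm(length(y2)) + (y2 == "TN") * runif(1, 0, 1)
    p <- per_feature_pvalue(x, y2, "tn_binary")
    p_ref <- stats::t.test(x ~ y2, var.equal = TRUE)$p.value
    expect_equal(p, p_ref, tolerance = 1e-10)
  }
  # degenerate and extreme inputs
  expect_equal(per_feature_pvalue(rep(3, 36), y2, "tn_binary"), 1)
  x_sep <- c(rnorm(24), rnorm(12) + 10)
  expect_lt(per_feature_pvalue(x_sep, y2, "tn_binary"), 1e-10)
  expect_error(per_feature_pvalue(1:4, factor(c("a", "a", "a", "b"))),
               ">= 2")
})

test_that("single-feature CV error is sane, stratified and deterministic", {
  y <- factor(rep(c("nonTN", "TN"), c(30, 30)))
  x_sep <- c(rnorm(30), rnorm(30) + 50)
  expect_equal(per_feature_cv_error(x_sep, y, seed = 2), 0)
  x_noise <- rnorm(60)
  expect_identical(per_feature_cv_error(x_noise, y, seed = 7),
                   per_feature_cv_error(x_noise, y, seed = 7))
  # chance level on label-independent noise, 4 balanced classes
  set.seed(61)
  y4 <- factor(rep(subtype_levels(), each = 30))
  errs <- replicate(30, per_feature_cv_error(rnorm(120), y4, seed = 3))
  expect_gt(mean(errs), 0.75 - 3 * sqrt(0.75 * 0.25 / 120) - 0.02)
  expect_lt(mean(errs), 0.75 + 3 * sqrt(0.75 * 0.25 / 120) + 0.02)
})

test_that("the elliptical gate is strict, correct and monotone", {
  expect_true(ellipse_accept(0, 0, c(0.6, 0.85)))
  expect_false(ellipse_accept(0.6, 0, c(0.6, 0.85)))   # boundary rejected
  expect_false(ellipse_accept(0, 0.85, c(0.6, 0.85)))
  expect_true(ellipse_accept(0.3, 0.4, c(0.6, 0.85)))  # 0.4715 < 1
  expect_equal((0.3 / 0.6)^2 + (0.4 / 0.85)^2, 0.4715, tolerance = 1e-4)
  # componentwise monotonicity on a random grid
  set.seed(62)
  for (rep in 1:200) {
    p2 <- runif(1); e2 <- runif(1)
    p1 <- runif(1, 0, p2); e1 <- runif(1, 0, e2)
    f <- c(runif(1, 0.05, 1), runif(1, 0.05, 1))
    if (ellipse_accept(p2, e2, f)) expect_true(ellipse_accept(p1, e1, f))
  }
  # acceptance count grows with a and with b
  set.seed(63)
  p <- runif(500); e <- runif(500)
  n_small <- sum(ellipse_accept(p, e, c(0.3, 0.5)))
  n_mid <- sum(ellipse_accept(p, e, c(0.6, 0.5)))
  n_big <- sum(ellipse_accept(p, e, c(0.6, 0.9)))
  expect_true(n_small <= n_mid && n_mid <= n_big)
})

test_that("acceptance-factor tuning hits the target retention with tie-breaks", {
  # all criteria at the origin: every grid point retains everything; the
  # area-then-a tie-break forces (0.01, 0.01)
  crit0 <- data.frame(p_value = rep(0, 10), cv_error = rep(0, 10))
  expect_equal(tune_acceptance_factors(crit0), c(a = 0.01, b = 0.01))

  # uniform criteria: retained fraction lands near the target
  set.seed(64)
  crit <- data.frame(p_value = runif(1000), cv_error = runif(1000))
  ab <- tune_acceptance_factors(crit)
  frac <- mean(ellipse_accept(crit$p_value, crit$cv_error, ab))
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)

  # single criterion: exhaustive grid oracle
  crit1 <- data.frame(p_value = 0.5, cv_error = 0.5)
  ab1 <- tune_acceptance_factors(crit1)
  grid <- seq(0.01, 1, by = 0.01)
  cand <- expand.grid(a = grid, b = grid)
  cand <- cand[(0.5 / cand$a)^2 + (0.5 / cand$b)^2 < 1, ]
  cand <- cand[order(cand$a * cand$b, cand$a), ]
  expect_equal(unname(ab1), unname(unlist(cand[1, ])), tolerance = 1e-12)
})

test_that("regularized rankings surface planted signal; fusion sums ranks", {
  set.seed(65)
  ok <- 0
  for (rep in 1:5) {
    n <- 80
    y <- factor(rep(c("nonTN", "TN"), each = n / 2))
    X <- matrix(rnorm(n * 30), n, 30)
    X[, 7] <- X[, 7] + (y == "TN") * 3
    colnames(X) <- paste0("f", 1:30)
    r <- regularized_rankings(scale(X), y, seed = rep)
    if (all(r[7, ] == 1)) ok <- ok + 1
  }
  expect_gte(ok, 4)  # the aligned column leads all three rankings

  # ridge splits weight across duplicated informative columns
  set.seed(66)
  n <- 100
  y <- factor(rep(c("nonTN", "TN"), each = n / 2))
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 3] <- rnorm(n, sd = 0.1) + (y == "TN") * 2
  X[, 4] <- X[, 3] + rnorm(n, sd = 0.05)
  colnames(X) <- paste0("f", 1:20)
  r <- regularized_rankings(scale(X), y, seed = 1)
  expect_true(all(r[3:4, "ridge"] <= 3))

  expect_equal(rank_fusion(cbind(c(1, 2), c(1, 2), c(1, 2))), c(3, 6))
  expect_equal(rank_fusion(list(c(1, 3, 2), c(1, 3, 2), c(1, 3, 2))),
               c(3, 9, 6))
  # B with ranks (2,2,2)=6 beats A with (1,3,3)=7
  expect_lt(rank_fusion(rbind(A = c(1, 3, 3), B = c(2, 2, 2)))[["B"]],
            rank_fusion(rbind(A = c(1, 3, 3), B = c(2, 2, 2)))[["A"]])
  expect_error(rank_fusion(list(1:3, 1:4, 1:3)), "mismatch")
  # fusion is invariant to method order
  r3 <- cbind(a = c(1, 2, 3), b = c(3, 1, 2), c = c(2, 3, 1))
  expect_equal(rank_fusion(r3), rank_fusion(r3[, c(3, 1, 2)]))
})

test_that("correlation pruning keeps one survivor per correlated block", {
  set.seed(67)
  # identical duplicate is removed
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  X[, 2] <- X[, 1]
  expect_identical(correlation_prune(X, paste0("f", 1:4), 0.4, 4),
                   c("f1", "f3", "f4"))
  # independent columns: first k kept in order
  X2 <- matrix(rnorm(50 * 10), 50, 10,
               dimnames = list(NULL, paste0("g", 1:10)))
  expect_identical(correlation_prune(X2, paste0("g", 10:1), 0.4, 5),
                   paste0("g", 10:6))
  # blocks of 4 at r ~ 0.9: exactly one survivor per block
  tb <- generate_feature_table(table_spec(
    n_subjects = 150, n_features = 16, n_informative = 0,
    n_correlated_blocks = 4, block_size = 4, block_correlation = 0.9,
    seed = 8))
  ids <- tb$meta$name
  kept <- suppressMessages(correlation_prune(tb$values, ids, 0.4, 16))
  blocks <- tb$meta$base_feature[match(kept, tb$meta$name)]
  expect_identical(sort(unique(blocks)), sort(unique(tb$meta$base_feature)))
  expect_identical(anyDuplicated(blocks), 0L)
  # matches the independent oracle on random input
  X3 <- matrix(rnorm(60 * 12), 60, 12,
               dimnames = list(NULL, paste0("h", 1:12)))
  X3[, 5] <- X3[, 2] * 0.9 + rnorm(60, sd = 0.1)
  ids3 <- sample(colnames(X3))
  expect_identical(correlation_prune(X3, ids3, 0.4, 6),
                   oracle_prune(X3, ids3, 0.4, 6))
})

test_that("two-stage selection composes, is reproducible, and bounds correlation", {
  tb <- generate_feature_table(table_spec(
    n_subjects = 134, n_features = 200, n_informative = 8, effect_size = 1,
    seed = 9))
  cfg <- pipeline_config("four_class", seed = 9)
  s1 <- two_stage_select(tb, cfg)
  s2 <- two_stage_select(tb, cfg)
  expect_identical(s1$final_features, s2$final_features)
  expect_identical(s1$fused_scores, s2$fused_scores)
  expect_true(all(s1$final_features %in% s1$top_k))
  expect_true(all(s1$top_k %in% s1$coarse_accepted))
  expect_lte(length(s1$final_features), cfg$final_feature_count)
  # final set honours the pairwise correlation bound
  C <- abs(stats::cor(tb$values[, s1$final_features]))
  diag(C) <- 0
  expect_lte(max(C), cfg$corr_threshold)

  # small-P degeneracy: P < top_k runs through without error
  tb_small <- generate_feature_table(table_spec(
    n_subjects = 60, n_features = 12, n_informative = 3, seed = 10))
  s3 <- suppressMessages(two_stage_select(tb_small,
                                          pipeline_config("four_class",
                                                          seed = 10)))
  expect_true(all(s3$final_features %in% tb_small$meta$name))
})

test_that("the Rad-score is the fitted linear combination and orders classes", {
  tb <- generate_feature_table(table_spec(
    n_subjects = 100, n_features = 12, n_informative = 6, effect_size = 1.2,
    seed = 12))
  cfg <- pipeline_config("tn_binary", seed = 12)
  sel <- suppressMessages(two_stage_select(tb, cfg))
  rs <- rad_score(tb, sel)
  # linearity: scores reproduce intercept + standardized X %*% beta
  Xs <- scale(tb$values[, rs$features, drop = FALSE])
  expect_equal(unname(rs$scores),
               unname(drop(rs$intercept + Xs %*% rs$coefficients)),
               tolerance = 1e-12)
  # the TN group mean score exceeds the non-TN mean (TN coded 1)
  expect_gt(mean(rs$scores[tb$labels == "TN"]),
            mean(rs$scores[tb$labels != "TN"]))
  # four-class variant returns the first discriminant axis
  cfg4 <- pipeline_config("four_class", seed = 12)
  sel4 <- suppressMessages(two_stage_select(tb, cfg4))
  rs4 <- rad_score(tb, sel4)
  expect_length(rs4$coefficients, length(sel4$final_features))
  expect_equal(length(rs4$scores), 100)
})
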