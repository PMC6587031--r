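test_that("the model zoo has exactly the 20 pinned classifiers", {
  zoo <- build_model_zoo("four_class")
  expect_length(zoo, 20)
  expect_identical(anyDuplicated(names(zoo)), 0L)
  fams <- table(vapply(zoo, `[[`, "", "family"))
  expect_identical(unname(fams[["tree"]]), 3L)
  expect_identical(unname(fams[["svm"]]), 6L)
  expect_identical(unname(fams[["knn"]]) + unname(fams[["wknn"]]), 4L)
  expect_identical(unname(fams[["subspace"]]) + unname(fams[["boost"]]) +
                     unname(fams[["bag"]]), 5L)
})

test_that("stratified folds keep class proportions within one subject", {
  y <- factor(rep(c("LuminalA", "LuminalB", "HER2pos", "TN"),
                  c(26, 68, 18, 22)))
  f <- stratified_folds(y, 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  for (cl in levels(y)) {
    per_fold <- table(factor(f[y == cl], levels = 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_identical(stratified_folds(y, 5, seed = 3),
                   stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(factor(c("a", "b", "b", "b")), 2),
               "at least as many")
})

test_that("coarse KNN caps k at the training size; every model predicts", {
  set.seed(70)
  n <- 40
  y <- factor(rep(c("nonTN", "TN"), each = n / 2))
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  zoo <- build_model_zoo("tn_binary")
  for (z in zoo) {
    pred <- predict_model(z, X[1:30, ], y[1:30], X[31:40, ], seed = 1)
    expect_s3_class(pred, "factor")
    expect_length(pred, 10)
    expect_false(any(is.na(pred)))
  }
})

test_that("LDA separates well-separated Gaussian blobs near perfectly", {
  set.seed(71)
  n <- 100
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5)
  X[y == "B", 1] <- X[y == "B", 1] + 8
  colnames(X) <- paste0("f", 1:5)
  rep <- repeated_cv_accuracy(X, y, build_model_zoo("tn_binary")["lda"],
                              cv_plan(5, 3, seed = 4))
  expect_gte(rep$accuracy[["lda"]], 0.98)
})

test_that("the harness is deterministic and pools fold accuracies correctly", {
  set.seed(72)
  n <- 60
  y <- factor(rep(subtype_levels(), each = n / 4))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + as.integer(factor(y, levels = subtype_levels()))
  zoo <- build_model_zoo("four_class")[c("lda", "coarse_tree",
                                         "ens_subspace_knn")]
  r1 <- repeated_cv_accuracy(X, y, zoo, cv_plan(5, 2, seed = 5))
  r2 <- repeated_cv_accuracy(X, y, zoo, cv_plan(5, 2, seed = 5))
  expect_identical(r1$per_round, r2$per_round)
  expect_equal(r1$accuracy, colMeans(r1$per_round), tolerance = 1e-12)
  # confusion rows sum to the class counts; accuracy is pooled correct / N
  for (nm in names(zoo)) {
    cm <- r1$confusion[[nm]]
    expect_equal(unname(rowSums(cm)), unname(table(y)), ignore_attr = TRUE)
    expect_equal(sum(diag(cm)) / n, unname(r1$per_round[2, nm]),
                 tolerance = 1e-12)
  }
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
})

test_that("best_model returns all tied maxima", {
  rep1 <- structure(list(accuracy = c(A = 0.7, B = 0.9)), class = "model_report")
  expect_identical(best_model(rep1)$names, "B")
  expect_equal(best_model(rep1)$accuracy, 0.9)
  rep2 <- structure(list(accuracy = c(lda = 0.724, sub = 0.724, qda = 0.70)),
                    class = "model_report")
  expect_identical(best_model(rep2)$names, c("lda", "sub"))
  rep3 <- structure(list(accuracy = c(only = 0.5)), class = "model_report")
  expect_identical(best_model(rep3)$names, "only")
})
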