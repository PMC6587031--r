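#' Build the 20-classifier model zoo
#'
#' The comparison set spans five families: three decision trees
#' (fine/medium/coarse = at most 100/20/4 splits), two discriminant models
#' (LDA, QDA), six SVMs (linear; polynomial degree 2 and 3; Gaussian with
#' kernel scale sqrt(P)/4, sqrt(P), 4 sqrt(P)), four KNNs (k = 1, 10, 100,
#' capped at n_train - 1, plus a squared-inverse-distance weighted k = 10)
#' and five ensembles of 30 learners (random-subspace LDA and 1-NN with
#' subspace dimension ceil(P/2); AdaBoost and RUSBoost on 20-split trees at
#' learning rate 0.1; bagged unpruned trees).
#'
#' @param task `"four_class"` or `"tn_binary"` (recorded in each spec).
#' @return Named list of 20 model specs.
#' @export
build_model_zoo <- function(task = c("four_class", "tn_binary")) {
  task <- match.arg(task)
  spec <- function(name, family, ...)
    list(name = name, family = family, task = task, params = list(...))
  zoo <- list(
    spec("fine_tree", "tree", max_splits = 100),
    spec("medium_tree", "tree", max_splits = 20),
    spec("coarse_tree", "tree", max_splits = 4),
    spec("lda", "lda"),
    spec("qda", "qda"),
    spec("svm_linear", "svm", kernel = "linear"),
    spec("svm_quadratic", "svm", kernel = "polynomial", degree = 2),
    spec("svm_cubic", "svm", kernel = "polynomial", degree = 3),
    spec("svm_fine_gaussian", "svm", kernel = "radial", scale_mult = 0.25),
    spec("svm_medium_gaussian", "svm", kernel = "radial", scale_mult = 1),
    spec("svm_coarse_gaussian", "svm", kernel = "radial", scale_mult = 4),
    spec("knn_fine", "knn", k = 1),
    spec("knn_medium", "knn", k = 10),
    spec("knn_coarse", "knn", k = 100),
    spec("knn_weighted", "wknn", k = 10),
    spec("ens_subspace_discriminant", "subspace", base = "lda", n_learners = 30),
    spec("ens_subspace_knn", "subspace", base = "knn1", n_learners = 30),
    spec("ens_adaboost_tree", "boost", rus = FALSE, n_learners = 30,
         learn_rate = 0.1, max_splits = 20),
    spec("ens_bagged_tree", "bag", n_learners = 30),
    spec("ens_rusboost_tree", "boost", rus = TRUE, n_learners = 30,
         learn_rate = 0.1, max_splits = 20)
  )
  names(zoo) <- vapply(zoo, `[[`, "", "name")
  stopifnot(length(zoo) == 20L)
  zoo
}

# ---- internal learners ------------------------------------------------------

fit_pruned_tree <- function(X, y, max_splits, weights = NULL) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  ctl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                              maxcompete = 0, maxsurrogate = 0)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
                      control = ctl)
  cpt <- fit$cptable
  ok <- which(cpt[, "nsplit"] <= max_splits)
  if (length(ok) && max(cpt[, "nsplit"]) > max_splits)
    fit <- rpart::prune(fit, cp = cpt[ok[length(ok)], "CP"])
  fit
}

predict_tree <- function(fit, Xte)
  predict(fit, data.frame(Xte, check.names = FALSE), type = "class")

majority_class <- function(y) factor(names(which.max(table(y))), levels(y))

safe_lda <- function(Xtr, ytr, Xte) {
  fit <- tryCatch(suppressWarnings(MASS::lda(Xtr, grouping = ytr)),
                  error = function(e) NULL)
  if (is.null(fit))  # within-group constant feature: shrunken pooled LDA
    return(rlda_predict(Xtr, ytr, Xte))
  predict(fit, Xte)$class
}

# pooled-covariance linear discriminant with diagonal shrinkage, used when
# MASS::lda rejects (near-)constant within-group features
rlda_predict <- function(Xtr, ytr, Xte) {
  lv <- levels(ytr)
  p <- ncol(Xtr)
  S <- matrix(0, p, p)
  mus <- matrix(0, length(lv), p)
  for (ci in seq_along(lv)) {
    Xc <- Xtr[ytr == lv[ci], , drop = FALSE]
    mus[ci, ] <- colMeans(Xc)
    S <- S + crossprod(sweep(Xc, 2, mus[ci, ]))
  }
  S <- S / max(nrow(Xtr) - length(lv), 1)
  S <- S + diag(1e-3 * mean(diag(S)) + 1e-8, p)
  Sinv <- solve(S)
  scores <- Xte %*% Sinv %*% t(mus)
  scores <- sweep(scores, 2, 0.5 * rowSums((mus %*% Sinv) * mus), `-`)
  scores <- sweep(scores, 2, log(as.vector(table(ytr)) / length(ytr)), `+`)
  factor(lv[max.col(scores, ties.method = "first")], lv)
}

# Gaussian QDA with diagonal shrinkage, used when MASS::qda is singular
# (small classes relative to the feature count)
rqda_predict <- function(Xtr, ytr, Xte) {
  lv <- levels(ytr)
  p <- ncol(Xtr)
  scores <- matrix(-Inf, nrow(Xte), length(lv))
  for (ci in seq_along(lv)) {
    Xc <- Xtr[ytr == lv[ci], , drop = FALSE]
    mu <- colMeans(Xc)
    S <- if (nrow(Xc) > 1) stats::cov(Xc) else diag(p)
    lam <- 1e-3 * mean(diag(S)) + 1e-8
    S <- S + diag(lam, p)
    ch <- chol(S)
    dev <- sweep(Xte, 2, mu)
    z <- forwardsolve(t(ch), t(dev))
    scores[, ci] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) +
      log(mean(ytr == lv[ci]))
  }
  factor(lv[max.col(scores)], lv)
}

weighted_knn_predict <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  lv <- levels(ytr)
  pred <- character(nrow(Xte))
  sq_tr <- rowSums(Xtr^2)
  for (i in seq_len(nrow(Xte))) {
    d2 <- pmax(sq_tr - 2 * drop(Xtr %*% Xte[i, ]) + sum(Xte[i, ]^2), 0)
    nb <- order(d2)[seq_len(k)]
    w <- 1 / pmax(d2[nb], 1e-12)
    pred[i] <- lv[which.max(vapply(lv, function(cl)
      sum(w[ytr[nb] == cl]), 0))]
  }
  factor(pred, lv)
}

subspace_ensemble_predict <- function(Xtr, ytr, Xte, base, n_learners, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- ncol(Xtr)
  dim_sub <- max(1L, ceiling(p / 2))
  lv <- levels(ytr)
  votes <- matrix(0, nrow(Xte), length(lv))
  for (b in seq_len(n_learners)) {
    fs <- sample.int(p, dim_sub)
    pr <- if (base == "lda")
      safe_lda(Xtr[, fs, drop = FALSE], ytr, Xte[, fs, drop = FALSE])
    else
      class::knn(Xtr[, fs, drop = FALSE], Xte[, fs, drop = FALSE], ytr, k = 1)
    votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] <-
      votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] + 1
  }
  factor(lv[max.col(votes, ties.method = "first")], lv)
}

# SAMME boosting over depth-limited trees; with `rus = TRUE` each round is
# fit on a class-balanced random undersample (weight-proportional)
boost_predict <- function(Xtr, ytr, Xte, n_learners, learn_rate, max_splits,
                          rus, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(Xtr)
  lv <- levels(ytr)
  K <- length(lv)
  w <- rep(1 / n, n)
  agg <- matrix(0, nrow(Xte), K)
  n_min <- min(table(ytr))
  for (m in seq_len(n_learners)) {
    if (rus) {
      take <- unlist(lapply(lv, function(cl) {
        idx <- which(ytr == cl)
        if (length(idx) <= n_min) idx
        else sample(idx, n_min, prob = w[idx] / sum(w[idx]))
      }))
      fit <- fit_pruned_tree(Xtr[take, , drop = FALSE], ytr[take], max_splits,
                             weights = NULL)
    } else {
      fit <- fit_pruned_tree(Xtr, ytr, max_splits, weights = w * n)
    }
    pr_tr <- predict_tree(fit, Xtr)
    err <- sum(w[pr_tr != ytr])
    if (err <= 0) err <- 1e-10
    if (err >= 1 - 1 / K) { w <- rep(1 / n, n); next }
    alpha <- learn_rate * (log((1 - err) / err) + log(K - 1))
    w <- w * exp(alpha * (pr_tr != ytr))
    w <- w / sum(w)
    pr_te <- predict_tree(fit, Xte)
    agg[cbind(seq_len(nrow(Xte)), as.integer(pr_te))] <-
      agg[cbind(seq_len(nrow(Xte)), as.integer(pr_te))] + alpha
  }
  if (all(agg == 0)) return(rep(majority_class(ytr), nrow(Xte)))
  factor(lv[max.col(agg, ties.method = "first")], lv)
}

#' Fit a model spec on training data and predict test labels
#'
#' @param spec one element of [build_model_zoo()].
#' @param Xtr,ytr training matrix (standardized) and factor labels.
#' @param Xte test matrix on the training standardization.
#' @param seed integer seed for stochastic learners (ensembles).
#' @return Factor of predicted labels with the levels of `ytr`.
#' @export
predict_model <- function(spec, Xtr, ytr, Xte, seed = 1L) {
  ytr <- droplevels(as.factor(ytr))
  p <- ncol(Xtr)
  pm <- spec$params
  out <- switch(
    spec$family,
    tree = predict_tree(fit_pruned_tree(Xtr, ytr, pm$max_splits), Xte),
    lda = safe_lda(Xtr, ytr, Xte),
    qda = {
      fit <- tryCatch(suppressWarnings(MASS::qda(Xtr, grouping = ytr)),
                      error = function(e) NULL)
      if (is.null(fit)) rqda_predict(Xtr, ytr, Xte)
      else predict(fit, Xte)$class
    },
    svm = {
      args <- list(x = Xtr, y = ytr, type = "C-classification",
                   kernel = pm$kernel, cost = 1, scale = FALSE)
      if (pm$kernel == "polynomial") {
        args$degree <- pm$degree; args$gamma <- 1 / p; args$coef0 <- 1
      }
      if (pm$kernel == "radial")
        args$gamma <- 1 / (pm$scale_mult * sqrt(p))^2
      fit <- do.call(e1071::svm, args)
      predict(fit, Xte)
    },
    knn = class::knn(Xtr, Xte, ytr, k = min(pm$k, nrow(Xtr) - 1L)),
    wknn = weighted_knn_predict(Xtr, ytr, Xte, pm$k),
    subspace = subspace_ensemble_predict(Xtr, ytr, Xte, pm$base,
                                         pm$n_learners, seed),
    boost = boost_predict(Xtr, ytr, Xte, pm$n_learners, pm$learn_rate,
                          pm$max_splits, pm$rus, seed),
    bag = {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      fit <- randomForest::randomForest(Xtr, ytr, ntree = pm$n_learners,
                                        mtry = p)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      predict(fit, Xte)
    },
    stop("unknown model family: ", spec$family)
  )
  factor(as.character(out), levels(ytr))
}

#' Cross-validation plan
#'
#' @param folds number of stratified folds (>= 2).
#' @param rounds number of repeats with re-drawn fold assignments.
#' @param seed integer seed; round r uses `seed + r` for its folds.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(folds = 5L, rounds = 10L, seed = 1L) {
  if (folds < 2) stop("`folds` must be >= 2")
  if (rounds < 1) stop("`rounds` must be >= 1")
  structure(list(folds = as.integer(folds), rounds = as.integer(rounds),
                 seed = as.integer(seed)), class = "cv_plan")
}

#' Repeated stratified cross-validated accuracy of a model zoo
#'
#' Per round: a fresh stratified fold assignment; each model is fit on 4/5
#' of the subjects (features standardized within the training folds) and
#' scored on the held-out fold; the round's accuracy pools correct
#' predictions over folds. The report averages over rounds.
#'
#' @param X numeric feature matrix (subjects x features).
#' @param labels class labels; every class needs >= `plan$folds` members.
#' @param zoo model list from [build_model_zoo()].
#' @param plan a [cv_plan()].
#' @return An object of class `model_report`: `accuracy` (named mean
#'   accuracies), `per_round` (rounds x models matrix), `confusion` (list of
#'   per-model confusion matrices summed over the last round's folds) and
#'   the plan.
#' @export
repeated_cv_accuracy <- function(X, labels, zoo = build_model_zoo(),
                                 plan = cv_plan()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(labels))
  if (any(table(y) < plan$folds))
    stop("every class needs at least as many members as folds")
  n <- nrow(X)
  model_names <- vapply(zoo, `[[`, "", "name")
  per_round <- matrix(NA_real_, plan$rounds, length(zoo),
                      dimnames = list(NULL, model_names))
  confusion <- NULL
  for (r in seq_len(plan$rounds)) {
    fold_id <- stratified_folds(y, plan$folds, plan$seed + r)
    correct <- stats::setNames(numeric(length(zoo)), model_names)
    conf <- lapply(zoo, function(z)
      matrix(0L, nlevels(y), nlevels(y),
             dimnames = list(truth = levels(y), pred = levels(y))))
    names(conf) <- model_names
    for (f in seq_len(plan$folds)) {
      tr <- fold_id != f
      ctr <- colMeans(X[tr, , drop = FALSE])
      scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      use <- scl > 0
      Xtr <- sweep(sweep(X[tr, use, drop = FALSE], 2, ctr[use]), 2,
                   scl[use], `/`)
      Xte <- sweep(sweep(X[!tr, use, drop = FALSE], 2, ctr[use]), 2,
                   scl[use], `/`)
      for (m in seq_along(zoo)) {
        pred <- predict_model(zoo[[m]], Xtr, y[tr], Xte,
                              seed = plan$seed + 1000L * r + 10L * f + m)
        correct[m] <- correct[m] + sum(pred == y[!tr])
        conf[[m]] <- conf[[m]] + unclass(table(truth = y[!tr], pred = pred))
      }
    }
    per_round[r, ] <- correct / n
    confusion <- conf
  }
  structure(list(accuracy = colMeans(per_round),
                 per_round = per_round,
                 confusion = confusion,
                 plan = plan,
                 n = n, classes = levels(y)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report: %d models, %d-fold CV x %d rounds, n = %d>\n",
              length(x$accuracy), x$plan$folds, x$plan$rounds, x$n))
  acc <- sort(x$accuracy, decreasing = TRUE)
  print(data.frame(model = names(acc),
                   accuracy = sprintf("%.1f%%", 100 * acc), row.names = NULL))
  invisible(x)
}

#' Best model(s) of a report
#'
#' @param report a `model_report`.
#' @return List with `names` (all models tied at the maximum, within 1e-12)
#'   and `accuracy`.
#' @export
best_model <- function(report) {
  stopifnot(length(report$accuracy) >= 1)
  mx <- max(report$accuracy)
  list(names = names(report$accuracy)[report$accuracy >= mx - 1e-12],
       accuracy = mx)
}
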