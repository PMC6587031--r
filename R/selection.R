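#' Per-feature hypothesis-test p-value
#'
#' One-way ANOVA F-test for the four-subtype task; two-sided pooled-variance
#' two-sample t-test for the binary task. A column that is constant across
#' all subjects carries no information and returns p = 1 by convention.
#'
#' @param column numeric feature values.
#' @param labels class labels (>= 2 groups, each with >= 2 observations).
#' @param task `"four_class"` or `"tn_binary"`.
#' @return p-value in `[0, 1]`.
#' @export
per_feature_pvalue <- function(column, labels,
                               task = c("four_class", "tn_binary")) {
  task <- match.arg(task)
  y <- as.factor(as.character(labels))
  if (nlevels(y) < 2 || any(table(y) < 2))
    stop("need >= 2 groups each with >= 2 observations")
  drop(per_feature_pvalues(matrix(column, ncol = 1), y))
}

# vectorized column-wise ANOVA-F / pooled-t p-values
per_feature_pvalues <- function(X, y) {
  y <- as.factor(y)
  n <- nrow(X); k <- nlevels(y)
  cnt <- as.vector(table(y))
  gsum <- rowsum(X, y)
  gmean <- gsum / cnt
  tot_mean <- colMeans(X)
  ssb <- colSums(cnt * (sweep(gmean, 2, tot_mean))^2)
  sst <- colSums(X^2) - n * tot_mean^2
  ssw <- pmax(sst - ssb, 0)
  p <- rep(1, ncol(X))
  if (k == 2) {
    # pooled-variance two-sample t, two-sided
    s2 <- ssw / (n - 2)
    d <- gmean[1, ] - gmean[2, ]
    se <- sqrt(s2 * (1 / cnt[1] + 1 / cnt[2]))
    ok <- se > 0
    p[ok] <- 2 * stats::pt(-abs(d[ok] / se[ok]), n - 2)
    p[!ok & abs(d) > 1e-12] <- 0
  } else {
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    ok <- ssw > 0
    p[ok] <- stats::pf(f[ok], k - 1, n - k, lower.tail = FALSE)
    p[!ok & ssb > 1e-12] <- 0
  }
  # constant columns (no variance at all) stay at p = 1
  p[sst <= .Machine$double.eps * n] <- 1
  p
}

#' Per-feature cross-validated error of a single-feature classifier
#'
#' Stratified k-fold error of a one-dimensional linear-discriminant
#' classifier (shared within-class variance, training-fold priors); the
#' coarse-stage "CV error" of each feature. A training fold with zero pooled
#' variance predicts its majority class.
#'
#' @param column numeric feature values.
#' @param labels class labels; each class needs >= `folds` members.
#' @param folds number of folds.
#' @param seed integer seed for the fold assignment.
#' @return Misclassification rate in `[0, 1]`.
#' @export
per_feature_cv_error <- function(column, labels, folds = 5L, seed = 1L) {
  y <- as.factor(as.character(labels))
  drop(per_feature_cv_errors(matrix(column, ncol = 1), y, folds, seed))
}

# vectorized column-wise stratified-CV error of univariate LDA
per_feature_cv_errors <- function(X, y, folds = 5L, seed = 1L) {
  y <- as.factor(y)
  fold_id <- stratified_folds(y, folds, seed)
  k <- nlevels(y)
  wrong <- numeric(ncol(X))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ytr <- y[tr]
    cnt <- as.vector(table(ytr))
    m <- rowsum(X[tr, , drop = FALSE], ytr) / cnt          # k x P class means
    # pooled within-class variance per column
    ssw <- colSums(X[tr, , drop = FALSE]^2) - colSums(cnt * m^2)
    s2 <- pmax(ssw / (sum(tr) - k), 0)
    logpri <- log(cnt / sum(cnt))
    Xte <- X[!tr, , drop = FALSE]
    best <- matrix(-Inf, nrow(Xte), ncol(Xte))
    pred <- matrix(1L, nrow(Xte), ncol(Xte))
    for (cl in seq_len(k)) {
      w <- ifelse(s2 > 0, m[cl, ] / s2, 0)
      b <- ifelse(s2 > 0, -m[cl, ]^2 / (2 * s2), 0) + logpri[cl]
      sc <- sweep(sweep(Xte, 2, w, `*`), 2, b, `+`)
      upd <- sc > best
      pred[upd] <- cl
      best[upd] <- sc[upd]
    }
    wrong <- wrong + colSums(pred != as.integer(y[!tr]))
  }
  wrong / length(y)
}

#' Elliptical acceptance gate for coarse feature selection
#'
#' A feature with test p-value p and single-feature CV error e is accepted
#' iff `(p/a)^2 + (e/b)^2 < 1` (strictly inside the ellipse with semi-axes
#' a and b; boundary points are rejected).
#'
#' @param p_value,cv_error numeric vectors in `[0, 1]` (recycled).
#' @param factors length-2 numeric (a, b), both in (0, 1].
#' @return Logical vector.
#' @export
ellipse_accept <- function(p_value, cv_error, factors) {
  a <- factors[[1]]; b <- factors[[2]]
  stopifnot(a > 0, b > 0)
  (p_value / a)^2 + (cv_error / b)^2 < 1
}

#' Grid-search the acceptance factors toward a target retention
#'
#' Ergodic scan of a, b over {0.01, 0.02, ..., 1.00}, minimizing the
#' distance between the retained count and `ceiling(target_fraction * P)`;
#' ties prefer the smaller ellipse area `a * b`, then the smaller a.
#'
#' @param criteria data.frame with columns `p_value` and `cv_error`.
#' @param target_fraction fraction of features to retain.
#' @return Named numeric (a, b).
#' @export
tune_acceptance_factors <- function(criteria, target_fraction = 0.5) {
  stopifnot(nrow(criteria) >= 1)
  grid <- seq(0.01, 1, by = 0.01)
  p2 <- criteria$p_value^2
  e2 <- criteria$cv_error^2
  target <- ceiling(target_fraction * nrow(criteria))
  inv_b2 <- 1 / grid^2
  best <- NULL
  for (a in grid) {
    u <- p2 / a^2
    # retained count for every b at once: P x 100
    cnt <- colSums(outer(u, rep(1, length(grid))) + outer(e2, inv_b2) < 1)
    for (bi in seq_along(grid)) {
      cand <- c(abs(cnt[bi] - target), a * grid[bi], a)
      if (is.null(best) ||
          cand[1] < best[1] - 1e-12 ||
          (abs(cand[1] - best[1]) < 1e-12 &&
           (cand[2] < best[2] - 1e-12 ||
            (abs(cand[2] - best[2]) < 1e-12 && cand[3] < best[3] - 1e-12)))) {
        best <- cand
        best_ab <- c(a = a, b = grid[bi])
      }
    }
  }
  best_ab
}

#' Rank features with three regularized linear models
#'
#' Fits L1 (lasso), L2 (ridge) and elastic-net (alpha = 0.5) penalized
#' logistic (binary) or multinomial (four-class) models with the penalty
#' strength chosen by internal 5-fold cross-validation, and ranks features
#' by the magnitude of the standardized coefficient at the selected penalty
#' (summed |coefficient| across classes for multinomial). Rank 1 = most
#' important; ties share the mean rank.
#'
#' @param X standardized (zero-mean, unit-variance columns) numeric matrix.
#' @param y class labels.
#' @param seed integer seed for the internal CV folds.
#' @return P x 3 matrix of ranks with columns lasso / ridge / elastic_net.
#' @export
regularized_rankings <- function(X, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (ncol(X) < 2) {
    out <- matrix(1, ncol(X), 3)
    colnames(out) <- c("lasso", "ridge", "elastic_net")
    rownames(out) <- colnames(X)
    return(out)
  }
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  foldid <- stratified_folds(y, 5L, seed)
  imp_one <- function(alpha) {
    fit <- suppressWarnings(
      glmnet::cv.glmnet(X, y, family = fam, alpha = alpha, foldid = foldid,
                        standardize = FALSE, nlambda = 60))
    cf <- glmnet::coef.glmnet(fit$glmnet.fit, s = fit$lambda.min)
    if (fam == "multinomial")
      Reduce(`+`, lapply(cf, function(m) abs(as.numeric(m)[-1])))
    else
      abs(as.numeric(cf)[-1])
  }
  ranks <- vapply(c(lasso = 1, ridge = 0, elastic_net = 0.5),
                  function(a) rank(-imp_one(a), ties.method = "average"),
                  numeric(ncol(X)))
  rownames(ranks) <- colnames(X)
  ranks
}

#' Fuse per-method ranks into a single score
#'
#' The score of each feature is the plain sum of its three method ranks;
#' smaller is better.
#'
#' @param ranks P x 3 matrix (or list of three equal-length rank vectors).
#' @return Numeric vector of fused scores.
#' @export
rank_fusion <- function(ranks) {
  if (is.list(ranks)) {
    if (length(unique(lengths(ranks))) != 1) stop("rank length mismatch")
    ranks <- do.call(cbind, ranks)
  }
  rowSums(ranks)
}

#' Greedy correlation pruning of a ranked shortlist
#'
#' Scans the shortlist in fused-score order, keeping a feature iff its
#' absolute Pearson correlation with every already-kept feature is at most
#' `threshold`, stopping at `final_count` features (or the end of the list,
#' with a message).
#'
#' @param X numeric matrix with named columns covering `ordered_ids`.
#' @param ordered_ids feature names in fused-score order (best first).
#' @param threshold maximum allowed absolute pairwise Pearson correlation.
#' @param final_count target number of surviving features.
#' @return Character vector of kept feature names.
#' @export
correlation_prune <- function(X, ordered_ids, threshold = 0.4,
                              final_count = 20L) {
  kept <- character(0)
  for (id in ordered_ids) {
    if (length(kept) >= final_count) break
    if (length(kept) == 0) { kept <- id; next }
    r <- suppressWarnings(
      abs(stats::cor(X[, id], X[, kept, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r <= threshold)) kept <- c(kept, id)
  }
  if (length(kept) < final_count)
    message(sprintf("correlation pruning kept %d features (target %d)",
                    length(kept), final_count))
  kept
}

#' Two-stage feature selection
#'
#' Stage 1 (coarse): a per-feature test p-value (ANOVA or t-test) and a
#' single-feature stratified-CV error are gated by the elliptical acceptance
#' domain. Stage 2 (fine): lasso, ridge and elastic-net rankings on the
#' standardized accepted features are fused by rank sum; the top
#' `fine_top_k` features are pruned greedily at `|Pearson r| <= threshold`
#' down to `final_feature_count`.
#'
#' @param table a [feature_table()].
#' @param config a [pipeline_config()].
#' @param auto_tune if `TRUE`, the acceptance factors are re-tuned on the
#'   observed criteria via [tune_acceptance_factors()] instead of using the
#'   configured values.
#' @return An object of class `selection_result` with elements
#'   `criteria`, `acceptance_factors`, `coarse_accepted`, `ranks`,
#'   `fused_scores`, `top_k`, `final_features`, `config`.
#' @export
two_stage_select <- function(table, config = pipeline_config(),
                             auto_tune = FALSE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "pipeline_config"))
  y <- task_labels(table$labels, config$task)
  X <- table$values

  p <- per_feature_pvalues(X, y)
  e <- per_feature_cv_errors(X, y, config$cv_folds, config$seed)
  criteria <- data.frame(feature = colnames(X), p_value = p, cv_error = e,
                         stringsAsFactors = FALSE)
  factors <- if (auto_tune) tune_acceptance_factors(criteria)
             else config$acceptance_factors
  acc <- ellipse_accept(p, e, factors)
  coarse <- colnames(X)[acc]
  if (length(coarse) == 0)
    stop("elliptical gate accepted no features")

  Xa <- scale(X[, coarse, drop = FALSE])
  Xa[, attr(Xa, "scaled:scale") == 0] <- 0
  ranks <- regularized_rankings(Xa, y, config$seed)
  fused <- rank_fusion(ranks)
  ord <- coarse[order(fused)]
  top_k <- ord[seq_len(min(config$fine_top_k, length(ord)))]
  final <- correlation_prune(X, top_k, config$corr_threshold,
                             config$final_feature_count)

  structure(list(criteria = criteria,
                 acceptance_factors = factors,
                 coarse_accepted = coarse,
                 ranks = ranks,
                 fused_scores = stats::setNames(fused, coarse),
                 top_k = top_k,
                 final_features = final,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result [%s]: %d coarse-accepted ",
                     "(a=%.2f, b=%.2f) -> top %d -> %d final>\n"),
              x$config$task, length(x$coarse_accepted),
              x$acceptance_factors[1], x$acceptance_factors[2],
              length(x$top_k), length(x$final_features)))
  invisible(x)
}

#' Rad-score: a weighted linear combination of the final features
#'
#' Binary task: a logistic model on the standardized final features; the
#' Rad-score is its linear predictor. Four-class task: the first linear
#' discriminant axis. If the fit is singular or separates perfectly, an L2
#' jitter (ridge penalty 1e-6) is applied.
#'
#' @param table a [feature_table()].
#' @param selection a `selection_result` (or character vector of feature
#'   names).
#' @param task `"four_class"` or `"tn_binary"`; defaults to the selection's.
#' @return An object of class `rad_score`: feature names, coefficients,
#'   intercept, per-subject scores, and the centers/scales used.
#' @export
rad_score <- function(table, selection, task = NULL) {
  stopifnot(inherits(table, "feature_table"))
  feats <- if (inherits(selection, "selection_result"))
    selection$final_features else as.character(selection)
  if (is.null(task))
    task <- if (inherits(selection, "selection_result"))
      selection$config$task else "four_class"
  y <- task_labels(table$labels, task)
  Xs <- scale(table$values[, feats, drop = FALSE])
  ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
  Xs[, scl == 0] <- 0

  if (task == "tn_binary") {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ Xs, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(stats::coef(fit))) ||
        any(is.na(stats::coef(fit))) || max(abs(stats::coef(fit)[-1])) > 1e3) {
      message("logistic fit degenerate; applying ridge jitter 1e-6")
      rfit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                             lambda = 1e-6, standardize = FALSE)
      cf <- as.numeric(glmnet::coef.glmnet(rfit))
    } else cf <- as.numeric(stats::coef(fit))
    intercept <- cf[1]; beta <- cf[-1]
  } else {
    fit <- tryCatch(suppressWarnings(MASS::lda(Xs, grouping = y)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      beta <- as.numeric(fit$scaling[, 1])
    } else {
      # a feature (near-)constant within groups: ridge-jittered Fisher axis
      message("discriminant fit degenerate; applying ridge jitter 1e-6")
      p <- ncol(Xs)
      W <- matrix(0, p, p); B <- matrix(0, p, p)
      gm <- colMeans(Xs)
      for (cl in levels(y)) {
        Xc <- Xs[y == cl, , drop = FALSE]
        dc <- sweep(Xc, 2, colMeans(Xc))
        W <- W + crossprod(dc)
        B <- B + nrow(Xc) * tcrossprod(colMeans(Xc) - gm)
      }
      beta <- as.numeric(eigen(solve(W + diag(1e-6, p), B))$vectors[, 1])
      beta <- Re(beta)
    }
    intercept <- -sum(colMeans(Xs) * beta)
  }
  scores <- drop(intercept + Xs %*% beta)
  structure(list(features = feats,
                 coefficients = stats::setNames(beta, feats),
                 intercept = intercept,
                 scores = stats::setNames(scores, table$subject_ids),
                 center = ctr, scale = scl, task = task),
            class = "rad_score")
}

#' @export
print.rad_score <- function(x, ...) {
  cat(sprintf("<rad_score [%s]: %d features>\n", x$task, length(x$features)))
  print(round(x$coefficients, 4))
  invisible(x)
}
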