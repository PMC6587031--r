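#' Stratified k-fold assignment
#'
#' Deals the members of each class into folds in shuffled round-robin order,
#' so every fold's class counts are within one subject of proportionality.
#'
#' @param y class labels (factor or character).
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in 1..k, one per observation.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  if (any(table(y) < k))
    stop("every class needs at least as many members as folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

task_labels <- function(labels, task) {
  if (task == "four_class")
    factor(labels, levels = subtype_levels())
  else
    factor(ifelse(labels == "TN", "TN", "nonTN"), levels = c("nonTN", "TN"))
}
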