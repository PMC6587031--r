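#!/usr/bin/env Rscript
# Step 3: the 20-classifier comparison on the selected features.
#
# Each model is evaluated by stratified 5-fold cross-validation repeated for
# 10 rounds (accuracy pooled over folds per round, averaged over rounds),
# for the four-subtype task and for TN vs non-TN, producing a model-by-task
# accuracy table.

suppressPackageStartupMessages(library(mrtraj))
seed <- 20260920L
tab <- read_feature_table("results/feature_table.csv")

acc <- list()
for (task in c("four_class", "tn_binary")) {
  sel <- jsonlite::fromJSON(sprintf("results/selection_%s.json", task))
  y <- if (task == "four_class") factor(tab$labels, subtype_levels())
       else factor(ifelse(tab$labels == "TN", "TN", "nonTN"))
  message("evaluating 20 classifiers [", task, "] ...")
  rep <- repeated_cv_accuracy(tab$values[, sel$final_features, drop = FALSE],
                              y, build_model_zoo(task),
                              cv_plan(5, 10, seed = seed))
  acc[[task]] <- rep$accuracy
  b <- best_model(rep)
  message(sprintf("  best: %s at %.1f%%",
                  paste(b$names, collapse = " & "), 100 * b$accuracy))
}

family <- c(rep("Decision tree", 3), rep("Discriminant analysis", 2),
            rep("SVM", 6), rep("KNN", 4), rep("Ensemble learning", 5))
out <- data.frame(family = family,
                  classifier = names(acc$four_class),
                  accuracy_four_class = sprintf("%.1f%%",
                                                100 * acc$four_class),
                  accuracy_tn_binary = sprintf("%.1f%%",
                                               100 * acc$tn_binary))
print(out, row.names = FALSE)
utils::write.csv(out, "results/model_accuracy.csv", row.names = FALSE)
message("wrote results/model_accuracy.csv")
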