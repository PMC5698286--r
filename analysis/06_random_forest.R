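#!/usr/bin/env Rscript
# Two-layer random-forest analysis on the simulated cohort: classify active
# vs inactive genes (all 79 features, mtry 20), regress log2 frequency of
# active genes, and run exhaustive subset selection over the top features.
# Writes results/rf/.

suppressPackageStartupMessages(library(kappaseq))

out <- "results/rf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fm_df <- read.table("results/features/feature_matrix.tsv", header = TRUE,
                    check.names = FALSE, colClasses = c(id = "character"))
fm <- as.matrix(fm_df[, -1])
rownames(fm) <- fm_df$id
calls <- read.table("results/quantify/activity_calls.tsv", header = TRUE,
                    colClasses = c(gene = "character"))
med <- read.table("results/quantify/median_frequency_J1.tsv", header = TRUE,
                  colClasses = c(gene = "character"))
active <- calls$active[match(rownames(fm), calls$gene)]

## Layer 1: classification (1000 trees per fold, 20 features per split)
folds_c <- make_folds(rownames(fm), k = 10, seed = 1)
rfc <- rf_classifier(fm, active, folds_c, n_trees = 1000, mtry = 20, seed = 2)
cat(sprintf("RF-C: accuracy %.1f%% (active %.1f%%, inactive %.1f%%), F1 %.3f\n",
            rfc$accuracy, rfc$active_accuracy, rfc$inactive_accuracy, rfc$f1))
imp_c <- rfc$importance[order(rfc$importance$mean, decreasing = TRUE), ]
cat("top 5 classification features:",
    paste(head(imp_c$feature, 5), collapse = ", "), "\n")
write.table(imp_c, file.path(out, "importance_classifier.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Layer 2: regression on active genes, log2 median frequency response
act_ids <- rownames(fm)[active]
freq <- med$median_frequency[match(act_ids, med$gene)]
keep <- freq > 0
y <- log2(freq[keep])
x <- fm[act_ids[keep], ]
folds_r <- make_folds(rownames(x), k = 10, seed = 3)
rfr <- rf_regressor(x, y, folds_r, n_trees = 1000, seed = 4)
cat(sprintf("RF-R: out-of-fold RMSE %.2f (a %.2f-fold typical error)\n",
            rfr$rmse, rmse_to_fold(rfr$rmse)))
imp_r <- rfr$importance[order(rfr$importance$mean, decreasing = TRUE), ]
write.table(imp_r, file.path(out, "importance_regressor.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Exhaustive subset selection over the top features (desk scale: top 6,
## 100 trees per fold; raise top_k/n_trees for a full-scale sweep)
ms <- model_selection(x, y, task = "regress", top_k = 6, folds = folds_r,
                      n_trees = 100, seed = 5,
                      initial_importance = rfr$importance)
best <- ms[which.min(ms$rmse), ]
top <- attr(ms, "top_features")
best_feats <- top[rev(strsplit(best$mask, "")[[1]])[seq_along(top)] == "1"]
cat(sprintf("best of %d subsets: RMSE %.2f (%.2f-fold) with {%s}\n",
            nrow(ms), best$rmse, rmse_to_fold(best$rmse),
            paste(best_feats, collapse = ", ")))
freq_incl <- inclusion_frequency(ms, metric = "rmse",
                                 threshold = quantile(ms$rmse, 0.1))
cat("inclusion frequency among the best-decile subsets:\n")
print(round(sort(freq_incl, decreasing = TRUE), 2))
write.table(ms, file.path(out, "model_selection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(classifier = list(accuracy = rfc$accuracy,
                         active_accuracy = rfc$active_accuracy,
                         inactive_accuracy = rfc$inactive_accuracy,
                         f1 = rfc$f1),
       regressor = list(rmse = rfr$rmse,
                        fold_error = rmse_to_fold(rfr$rmse)),
       best_subset = list(rmse = best$rmse, features = best_feats)),
  file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
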