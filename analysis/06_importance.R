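#!/usr/bin/env Rscript
# Stage 6: global feature importance via per-fold random forests and
# probability-space tree SHAP.
#
# One forest per fold on the representative continuous features plus the
# categorical indicators, trained only on that fold's balanced training
# set. Shapley attributions are computed for each fold's strict held-out
# transcripts (so no transcript is explained by a model that saw it), in
# probability units: baseline + sum(phi) = predicted coding probability.
# Global importance is the mean |phi| pooled over all out-of-fold
# transcripts, with per-fold spread.

suppressPackageStartupMessages(library(lncentropy))

feat <- read.delim("results/feature_matrix.tsv")
rownames(feat) <- feat$transcript_id
feat$transcript_id <- NULL
schema <- jsonlite::fromJSON("results/feature_matrix.schema.json")
prof <- read.delim("results/entropy_profiles.tsv")
clust_rep <- read.delim("results/enrichment_results.tsv")
man <- read.delim("results/fold_manifest.tsv")
preds <- read.delim("results/cohort/predictions.tsv")

ids <- prof$transcript_id
ft <- feature_table(feat[ids, schema$name, drop = FALSE], schema)
prep <- preprocess_features(ft)
reps <- unique(clust_rep$feature[clust_rep$test == "mann_whitney"])
x <- cbind(prep$continuous[, intersect(reps, colnames(prep$continuous)),
                           drop = FALSE],
           prep$indicators)
labels <- setNames(preds$reference_label, preds$transcript_id)[ids]

k <- max(man$fold) + 1L
folds <- lapply(seq_len(k) - 1L, function(fi) {
  pick <- function(role) {
    sub <- man[man$fold == fi & man$role == role & man$transcript_id %in% ids, ]
    split(sub$transcript_id, sub$class)
  }
  list(fold_index = fi, train_ids_by_class = pick("train"),
       test_ids_by_class = pick("test"),
       heldout_ids_by_class = pick("heldout"), k = k, seed = 1L)
})

fits <- train_forests(x, labels, folds, forest_config(n_trees = 500, seed = 1))
explanations <- lapply(seq_len(k), function(i) {
  held <- unlist(folds[[i]]$heldout_ids_by_class, use.names = FALSE)
  explain_forest(fits$folds[[i]], x[held, , drop = FALSE])
})

oof_acc <- vapply(seq_len(k), function(i) {
  e <- explanations[[i]]
  pred <- ifelse(e$prediction >= fits$folds[[i]]$threshold, "coding", "lncRNA")
  evaluate_predictions(pred, labels[e$ids])$balanced_accuracy
}, numeric(1))
cat(sprintf("Out-of-fold balanced accuracy: %.3f (sd %.3f over %d folds)\n",
            mean(oof_acc), sd(oof_acc), k))

imp <- summarize_importance(explanations)
data.table::fwrite(imp, "results/global_importance.tsv", sep = "\t")
cat("Top 10 features by mean |SHAP| (probability units):\n")
print(head(imp, 10), row.names = FALSE)

# waterfall view of one confidently-classified transcript
e1 <- explanations[[1]]
i_best <- which.max(abs(e1$prediction - 0.5))
tc <- top_contributions(e1, i_best)
cat(sprintf("\nExample transcript %s: baseline %.3f -> prediction %.3f\n",
            e1$ids[i_best], tc$baseline, tc$prediction))
print(round(tc$top, 4))
cat(sprintf("  + remainder of %d features: %+.4f\n", tc$n_aggregated, tc$remainder))

cat("\nGlobal importance written to results/global_importance.tsv\n")
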