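#!/usr/bin/env Rscript
# Stage 4: ensemble uncertainty decomposition and transcript stratification.
#
# For each transcript scored by all tools: mean coding probability, its
# Shannon entropy (H_pred), the mean per-tool entropy (H_exp), and the
# disagreement score I_dis = H_pred - H_exp. Transcripts are stratified per
# reference class: "low" below the class 10th percentile of H_pred, "high"
# above the class 90th percentiles of both H_pred and I_dis (strict
# inequalities). Inter-tool agreement and per-tool macro metrics round out
# the stage.

suppressPackageStartupMessages(library(lncentropy))

cohort_dir <- "results/cohort"
pred <- read.delim(file.path(cohort_dir, "predictions.tsv"))
man <- read.delim("results/fold_manifest.tsv")
ids <- intersect(pred$transcript_id, unique(man$transcript_id))
pred <- pred[match(ids, pred$transcript_id), ]

p <- as.matrix(pred[, grep("^p_", colnames(pred))])
rownames(p) <- ids
colnames(p) <- sub("^p_", "", colnames(p))
compl <- exclude_incomplete(p)
cat(sprintf("Scored by all %d tools: %d of %d (%d excluded)\n",
            ncol(p), nrow(compl$complete), length(ids),
            length(compl$excluded_ids)))

keep <- rownames(compl$complete)
refs <- setNames(pred$reference_label[match(keep, pred$transcript_id)], keep)
prof <- ensemble_profile(compl$complete)
thr <- compute_thresholds(prof, refs)
groups <- stratify_transcripts(prof, refs, thr)
cat("Stratification thresholds (per class):\n")
for (cl in names(thr)) {
  cat(sprintf("  %s: H_pred q10 = %.3f, q90 = %.3f; I_dis q90 = %.3f\n",
              cl, thr[[cl]]$q10_Hpred, thr[[cl]]$q90_Hpred, thr[[cl]]$q90_Idis))
}
print(table(group = groups, class = refs))

labels <- as.matrix(pred[match(keep, pred$transcript_id),
                         grep("^label_", colnames(pred))])
colnames(labels) <- sub("^label_", "", colnames(labels))
agree <- agreement_category(labels, refs)
cat("Agreement categories:\n")
print(round(100 * prop.table(table(agree$category)), 1))

metrics <- vapply(colnames(labels), function(tool)
  evaluate_predictions(labels[, tool], refs)$balanced_accuracy, numeric(1))
cat("Per-tool balanced accuracy:\n")
print(round(metrics, 3))

out <- cbind(transcript_id = keep, prof, group = as.character(groups),
             category = as.character(agree$category))
data.table::fwrite(out, "results/entropy_profiles.tsv", sep = "\t")
jsonlite::write_json(thr, "results/stratification_thresholds.json",
                     auto_unbox = TRUE, digits = NA)
cat("Profiles written to results/entropy_profiles.tsv\n")
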