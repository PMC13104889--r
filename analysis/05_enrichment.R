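#!/usr/bin/env Rscript
# Stage 5: feature redundancy reduction and univariate enrichment.
#
# Continuous features are clustered on a Spearman-derived distance
# (d = 1 - |rho|, Ward linkage, silhouette-chosen cut); one representative
# per cluster is kept (largest |cVDA| on the low-vs-high comparison).
# Representatives and categorical indicators are then tested across the
# entropy groups and classes: Mann-Whitney U + centered Vargha-Delaney A
# for continuous features, chi-squared + Cramer's V + odds ratio for
# indicators, BH-adjusted within each comparison (significant: p_adj < 0.01;
# non-negligible: effect > 0.1).

suppressPackageStartupMessages(library(lncentropy))

feat <- read.delim("results/feature_matrix.tsv")
rownames(feat) <- feat$transcript_id
feat$transcript_id <- NULL
schema <- jsonlite::fromJSON("results/feature_matrix.schema.json")
prof <- read.delim("results/entropy_profiles.tsv")

ids <- prof$transcript_id
ft <- feature_table(feat[ids, schema$name, drop = FALSE], schema)
prep <- preprocess_features(ft)
cat(sprintf("After preprocessing: %d continuous + %d indicator features (%d dropped)\n",
            ncol(prep$continuous), ncol(prep$indicators), nrow(prep$dropped)))

clustering <- cluster_features(prep$continuous)
cat(sprintf("Feature clustering: %d clusters at cut height %.3f\n",
            clustering$n_clusters, clustering$chosen_height))

groups <- factor(prof$group, levels = c("low", "intermediate", "high"))
classes <- read.delim("results/cohort/predictions.tsv")
classes <- setNames(classes$reference_label, classes$transcript_id)[ids]
effect <- vapply(colnames(prep$continuous), function(nm) {
  v <- prep$continuous[[nm]]
  mannwhitney_vda(v[groups == "low"], v[groups == "high"])$cVDA
}, numeric(1))
reps <- select_feature_representatives(clustering, "max_effect", effect = effect)
cat(sprintf("Representatives: %d features\n", length(reps)))

res <- run_enrichment(prep$continuous, prep$indicators, classes, groups,
                      features = reps)
data.table::fwrite(res, "results/enrichment_results.tsv", sep = "\t")
for (comp in unique(res$comparison)) {
  sub <- res[res$comparison == comp & res$significant & res$non_negligible, ]
  sub <- sub[order(-abs(sub$effect)), ]
  cat(sprintf("\n%s: %d significant non-negligible features; top 5 by effect:\n",
              comp, nrow(sub)))
  print(head(sub[, c("feature", "test", "effect", "p_adj")], 5), row.names = FALSE)
}
cat("\nResults written to results/enrichment_results.tsv\n")
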