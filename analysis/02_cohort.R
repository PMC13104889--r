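#!/usr/bin/env Rscript
# Stage 2: build the label-stable, redundancy-reduced benchmark set and the
# balanced 5-fold cross-validation splits.
#
# Transcripts must (a) keep the same protein-coding/lncRNA biotype in both
# annotation releases and (b) be the longest member of their sequence
# cluster. Training sets are class-balanced; test sets keep the cohort's
# class imbalance; each transcript has exactly one strict held-out fold.

suppressPackageStartupMessages(library(lncentropy))

cohort_dir <- "results/cohort"
rel_a <- read_annotation(file.path(cohort_dir, "release_a.tsv"), "relA")
rel_b <- read_annotation(file.path(cohort_dir, "release_b.tsv"), "relB")
stable <- intersect_releases(rel_a, rel_b)
cat(sprintf("Label-stable transcripts: %d of %d (%.1f%% churned out)\n",
            length(stable), nrow(rel_a),
            100 * (1 - length(stable) / nrow(rel_a))))

lengths <- setNames(rel_a$length, rel_a$transcript_id)
reps <- select_cluster_representatives(
  file.path(cohort_dir, "clusters.clstr"), lengths)
ids <- intersect(stable, reps)
cat(sprintf("Cluster representatives: %d; stable representatives: %d\n",
            length(reps), length(ids)))

biotype <- setNames(rel_a$biotype, rel_a$transcript_id)
class_of <- ifelse(biotype[ids] == "protein_coding", "coding", "lncRNA")
cat(sprintf("Benchmark set: %d coding + %d lncRNA\n",
            sum(class_of == "coding"), sum(class_of == "lncRNA")))

folds <- make_fold_splits(split(ids, class_of), k = 5, seed = 1)
man <- fold_manifest(folds)
data.table::fwrite(man, "results/fold_manifest.tsv", sep = "\t")
f1 <- folds[[1]]
cat(sprintf("Fold 1: train %d + %d (balanced), test %d, held-out %d\n",
            length(f1$train_ids_by_class[[1]]), length(f1$train_ids_by_class[[2]]),
            length(unlist(f1$test_ids_by_class)),
            length(unlist(f1$heldout_ids_by_class))))
cat("Fold manifest written to results/fold_manifest.tsv\n")
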