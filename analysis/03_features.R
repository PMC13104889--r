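#!/usr/bin/env Rscript
# Stage 3: extract the extended genomic feature sets.
#
# Repeat features come from RepeatMasker output: hits are parsed, overlaps
# resolved by alignment score (trim/drop), fragments aggregated into
# elements by the ID column, and transcript-level summaries computed
# (counts, coverage, gaps, repeat-free stretch, per-kb rates, divergence).
# Non-B DNA features come from motif BED calls intersected with gene
# bodies; overlapping calls are retained, so coverage can exceed 1. Both
# sets are appended to the simulated ML feature table.

suppressPackageStartupMessages(library(lncentropy))

cohort_dir <- "results/cohort"
man <- read.delim("results/fold_manifest.tsv")
ids <- sort(unique(man$transcript_id))
rel_a <- read_annotation(file.path(cohort_dir, "release_a.tsv"), "relA")
lengths <- setNames(rel_a$length, rel_a$transcript_id)[ids]

rep_mat <- repeat_feature_matrix(file.path(cohort_dir, "repeats.out"), lengths)
cat(sprintf("Repeat features: %d transcripts x %d features; %.0f%% carry a repeat\n",
            nrow(rep_mat), ncol(rep_mat), 100 * mean(rep_mat$total_hit_count > 0)))

genes <- read.delim(file.path(cohort_dir, "genes.bed"), header = FALSE,
                    col.names = c("chrom", "start", "end", "gene_id"))
genes <- genes[, c("gene_id", "chrom", "start", "end")]
nbd_mat <- nbd_feature_matrix(file.path(cohort_dir, "motifs.bed"), genes)
cat(sprintf("Non-B DNA features: %d genes x %d features; mean diversity %.2f\n",
            nrow(nbd_mat), ncol(nbd_mat), mean(nbd_mat$diversity)))

ml <- read.delim(file.path(cohort_dir, "features.tsv"))
rownames(ml) <- ml$transcript_id
ml$transcript_id <- NULL
meta <- jsonlite::fromJSON(file.path(cohort_dir, "features.schema.json"))

# genes are one-per-transcript in the synthetic cohort (G founded on T index)
gene_of <- setNames(genes$gene_id, sub("^G", "T", genes$gene_id))
nbd_tx <- nbd_mat[gene_of[ids], , drop = FALSE]
rownames(nbd_tx) <- ids

combined <- cbind(ml[ids, , drop = FALSE], rep_mat[ids, ], nbd_tx)
schema <- rbind(
  meta[, c("name", "kind", "source", "units")],
  data.frame(name = colnames(rep_mat), kind = "continuous", source = "repeat",
             units = repeat_feature_schema()$units),
  data.frame(name = colnames(nbd_mat), kind = "continuous", source = "nbd",
             units = nbd_feature_schema()$units))
ft <- feature_table(combined, schema)
data.table::fwrite(cbind(transcript_id = rownames(ft$data), ft$data),
                   "results/feature_matrix.tsv", sep = "\t")
jsonlite::write_json(ft$meta, "results/feature_matrix.schema.json",
                     dataframe = "rows")
cat(sprintf("Combined feature matrix: %d x %d written to results/feature_matrix.tsv\n",
            nrow(ft$data), ncol(ft$data)))
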