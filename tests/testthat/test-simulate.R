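test_that("identical seeds give identical cohorts; class counts are exact", {
  cfg <- tiny_config(seed = 33)
  a <- simulate_cohort(cfg, include_fasta = TRUE)
  b <- simulate_cohort(cfg, include_fasta = TRUE)
  expect_identical(a$predictions$p, b$predictions$p)
  expect_identical(a$features$table$data, b$features$table$data)
  expect_identical(a$annotations$repeat_text, b$annotations$repeat_text)
  expect_identical(as.character(a$annotations$fasta),
                   as.character(b$annotations$fasta))
  expect_equal(sum(a$reference_labels == "coding"), cfg$n_coding)
  expect_equal(sum(a$reference_labels == "lncRNA"), cfg$n_lnc)
  # different seed changes the draw
  c2 <- simulate_cohort(tiny_config(seed = 34), include_fasta = FALSE)
  expect_false(identical(a$predictions$p, c2$predictions$p))
})

test_that("noiseless strong-signal limit makes every tool agree with the reference", {
  cfg <- simulation_config(n_coding = 80, n_lnc = 60, n_tools = 4,
                           tool_noise = rep(0, 4), signal_scale = 30,
                           boundary_fraction = 0, seed = 2)
  pr <- generate_predictions(cfg)
  expect_true(all(pr$label == matrix(pr$reference_label, nrow(pr$label),
                                     ncol(pr$label))))
})

test_that("a pure boundary population is maximally uncertain", {
  cfg <- simulation_config(n_coding = 5000, n_lnc = 5000, n_tools = 8,
                           boundary_fraction = 1, signal_scale = 1e-3,
                           seed = 8)
  pr <- generate_predictions(cfg)
  prof <- ensemble_profile(pr$p)
  expect_equal(mean(prof$p_mean), 0.5, tolerance = 0.01)
  expect_gt(mean(prof$H_pred), 0.9)
})

test_that("planted missingness is recovered exactly by the exclusion filter", {
  cfg <- simulation_config(n_coding = 500, n_lnc = 500,
                           missing_fraction = 0.05, seed = 12)
  pr <- generate_predictions(cfg)
  ex <- exclude_incomplete(pr$p)
  expect_identical(rownames(ex$complete), pr$truth$complete_ids)
})

test_that("label churn controls the size of the stable intersection", {
  cfg <- simulation_config(n_coding = 600, n_lnc = 400,
                           churn_fraction = 0.1, seed = 19)
  an <- generate_annotations(cfg, include_fasta = FALSE)
  stable <- intersect_releases(an$release_a, an$release_b)
  expect_identical(sort(stable),
                   sort(setdiff(an$release_a$transcript_id, an$truth$churned_ids)))
  # binomial scale check at the configured churn rate
  expect_equal(length(stable), 900, tolerance = 0.05)
  # churn 0: everything is stable
  an0 <- generate_annotations(simulation_config(n_coding = 100, n_lnc = 50,
                                                churn_fraction = 0, seed = 19),
                              include_fasta = FALSE)
  expect_identical(intersect_releases(an0$release_a, an0$release_b),
                   an0$release_a$transcript_id)
})

test_that("increasing tool noise does not decrease mean disagreement", {
  means <- vapply(c(0.3, 0.6, 1.2, 2.4), function(s) {
    cfg <- simulation_config(n_coding = 1500, n_lnc = 1000, n_tools = 6,
                             tool_noise = rep(s, 6), seed = 77)
    mean(ensemble_profile(generate_predictions(cfg)$p)$I_dis)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("null feature generator yields no BH-significant features", {
  # all class shifts zero and equal categorical rates: across seeded
  # replicates the enrichment pipeline must stay at its nominal error rate
  n_rep <- 100
  n_sig <- integer(n_rep)
  n_feat <- integer(n_rep)
  any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_coding = 100, n_lnc = 100, n_feature_blocks = 5,
      block_sizes = rep(4L, 5), block_class_shift = rep(0, 5),
      n_categorical = 4,
      categorical_rates = cbind(rep(0.5, 4), rep(0.5, 4)),
      seed = 1000 + r)
    ff <- generate_features(cfg)
    prep <- preprocess_features(ff$table)
    groups <- factor(rep("low", 200), levels = c("low", "intermediate", "high"))
    labels <- ifelse(sim_labels(cfg) == "coding", "coding", "lncRNA")
    res <- run_enrichment(prep$continuous, prep$indicators, labels, groups,
                          comparisons = "lnc_vs_pc_low")
    n_sig[r] <- sum(res$significant)
    n_feat[r] <- nrow(res)
    any_sig[r] <- any(res$significant)
  }
  # no feature significant in at least 95% of replicates
  expect_gte(mean(!any_sig), 0.95)
  # overall flagged fraction bounded by the nominal rate + 3 s.e.
  frac <- sum(n_sig) / sum(n_feat)
  expect_lte(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / sum(n_feat)))
})

test_that("a planted quantile shift is recovered as the intended cVDA", {
  # one shifted block; shift chosen analytically so that
  # A = Phi(2 s / sqrt(2 * (1 + 0.2^2))) = 0.8, i.e. cVDA = 0.3
  target_a <- 0.8
  s <- qnorm(target_a) * sqrt(2 * 1.04) / 2
  cfg <- simulation_config(n_coding = 2000, n_lnc = 2000,
                           n_feature_blocks = 1, block_sizes = 1L,
                           block_class_shift = s, n_categorical = 0,
                           categorical_rates = matrix(numeric(0), 0, 2),
                           seed = 55)
  ff <- generate_features(cfg)
  labels <- sim_labels(cfg)
  v <- ff$table$data[[1]]
  est <- mannwhitney_vda(v[labels == "coding"], v[labels == "lncRNA"])$cVDA
  expect_lt(abs(est - 0.3), 0.05)
})

test_that("complete block separation gives cVDA = 0.5 for its features", {
  cfg <- simulation_config(n_coding = 150, n_lnc = 150,
                           n_feature_blocks = 1, block_sizes = 2L,
                           block_class_shift = 50, n_categorical = 0,
                           categorical_rates = matrix(numeric(0), 0, 2),
                           seed = 4)
  ff <- generate_features(cfg)
  labels <- sim_labels(cfg)
  for (j in 1:2) {
    v <- ff$table$data[[j]]
    expect_equal(mannwhitney_vda(v[labels == "coding"],
                                 v[labels == "lncRNA"])$cVDA, 0.5)
  }
})

test_that("generated feature blocks are recovered by the clustering stage", {
  # two size-5 blocks plus 3 independent features
  cfg <- simulation_config(n_coding = 200, n_lnc = 200,
                           n_feature_blocks = 5,
                           block_sizes = c(5L, 5L, 1L, 1L, 1L),
                           block_class_shift = c(0.5, 0.3, 0, 0, 0),
                           n_categorical = 0,
                           categorical_rates = matrix(numeric(0), 0, 2),
                           seed = 23)
  ff <- generate_features(cfg)
  m <- cluster_features(ff$table$data)$membership
  b1 <- m[grep("^blk01", names(m))]
  b2 <- m[grep("^blk02", names(m))]
  expect_length(unique(b1), 1)
  expect_length(unique(b2), 1)
  expect_false(b1[[1]] == b2[[1]])
})

test_that("written cohort artifacts round-trip through the parsers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 91)
  co <- simulate_cohort(cfg, include_fasta = TRUE)
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  # .out round trip
  hits <- parse_repeatmasker_out(file.path(dir, "repeats.out"))
  expect_equal(nrow(hits), nrow(co$annotations$repeat_hits))
  expect_equal(hits$begin, co$annotations$repeat_hits$begin)
  expect_equal(hits$end, co$annotations$repeat_hits$end)
  expect_equal(hits$element_id, co$annotations$repeat_hits$element_id)
  # BED round trip
  calls <- read_motif_bed(file.path(dir, "motifs.bed"))
  expect_equal(calls$start, co$annotations$motif_calls$start)
  expect_equal(calls$motif_type, co$annotations$motif_calls$motif_type)
  # .clstr round trip
  cl <- parse_clstr(file.path(dir, "clusters.clstr"))
  expect_setequal(cl$id, co$predictions$transcript_id)
  # FASTA lengths match the annotation lengths
  fa <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  expect_equal(unname(BiocGenerics::width(fa)),
               unname(co$annotations$lengths[names(fa)]))
})

test_that("non-finite or inconsistent configs are rejected", {
  expect_error(simulation_config(signal_scale = NaN), "non-finite")
  expect_error(simulation_config(boundary_fraction = 1.2))
  expect_error(simulation_config(n_tools = 3, tool_gain = c(1, 1)))
  expect_error(simulation_config(n_feature_blocks = 2, block_sizes = c(3L)))
})
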