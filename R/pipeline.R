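#' Configuration for an end-to-end benchmark run
#'
#' Collects every stage's knobs: the synthetic-cohort generator (or a
#' directory of pre-existing inputs in the generator's file layout), the
#' stratification quantiles, the enrichment thresholds, the forest
#' configuration, the number of folds, and the embedding switch. Stage seeds
#' derive from the simulation seed.
#'
#' @param sim a [simulation_config()] (used when `input_dir` is NULL).
#' @param input_dir optional directory with pre-existing inputs
#'   (`predictions.tsv`, `features.tsv` + schema, `release_a.tsv`,
#'   `release_b.tsv`, `clusters.clstr`, `repeats.out`, `motifs.bed`,
#'   `genes.bed`); when set, the simulate stage is skipped.
#' @param k number of cross-validation folds.
#' @param q_low,q_high stratification quantiles (defaults 0.10 / 0.90).
#' @param sig_alpha adjusted-p significance threshold (default 0.01).
#' @param effect_threshold non-negligible effect threshold (default 0.1).
#' @param forest a [forest_config()].
#' @param forced_representatives features forced as cluster representatives.
#' @param run_embedding logical; compute the t-SNE inspection embedding.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), input_dir = NULL,
                            k = 5, q_low = 0.10, q_high = 0.90,
                            sig_alpha = 0.01, effect_threshold = 0.1,
                            forest = forest_config(seed = sim$seed),
                            forced_representatives = character(),
                            run_embedding = FALSE) {
  stopifnot(inherits(sim, "simulation_config"), inherits(forest, "forest_config"))
  structure(list(sim = sim, input_dir = input_dir, k = as.integer(k),
                 q_low = q_low, q_high = q_high, sig_alpha = sig_alpha,
                 effect_threshold = effect_threshold, forest = forest,
                 forced_representatives = forced_representatives,
                 run_embedding = isTRUE(run_embedding)),
            class = "pipeline_config")
}

pipeline_inputs <- function(config, out_dir) {
  if (is.null(config$input_dir)) {
    cohort <- simulate_cohort(config$sim, include_fasta = FALSE)
    return(list(
      predictions = cohort$predictions,
      features = cohort$features$table,
      release_a = cohort$annotations$release_a,
      release_b = cohort$annotations$release_b,
      clstr = cohort$annotations$clstr_text,
      repeat_text = cohort$annotations$repeat_text,
      motif_calls = cohort$annotations$motif_calls,
      genes = cohort$annotations$genes,
      lengths = cohort$annotations$lengths
    ))
  }
  need <- c(predictions = "predictions.tsv", features = "features.tsv",
            schema = "features.schema.json", release_a = "release_a.tsv",
            release_b = "release_b.tsv", clstr = "clusters.clstr",
            repeats = "repeats.out", motifs = "motifs.bed",
            genes = "genes.bed")
  paths <- file.path(config$input_dir, need)
  names(paths) <- names(need)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file: ", missing[1])
  }
  pred_df <- as.data.frame(data.table::fread(paths[["predictions"]]))
  p_cols <- grep("^p_", colnames(pred_df), value = TRUE)
  l_cols <- grep("^label_", colnames(pred_df), value = TRUE)
  p <- as.matrix(pred_df[, p_cols])
  rownames(p) <- pred_df$transcript_id
  colnames(p) <- sub("^p_", "", p_cols)
  lab <- as.matrix(pred_df[, l_cols])
  dimnames(lab) <- dimnames(p)
  predictions <- structure(list(
    transcript_id = pred_df$transcript_id,
    reference_label = pred_df$reference_label,
    p = p, label = lab,
    tool_threshold = stats::setNames(rep(0.5, ncol(p)), colnames(p)),
    truth = NULL), class = "prediction_set")
  fdf <- as.data.frame(data.table::fread(paths[["features"]]))
  rownames(fdf) <- fdf$transcript_id
  fdf$transcript_id <- NULL
  meta <- jsonlite::fromJSON(paths[["schema"]])
  features <- feature_table(fdf[, meta$name, drop = FALSE], meta)
  release_a <- as.data.frame(data.table::fread(paths[["release_a"]]))
  release_b <- as.data.frame(data.table::fread(paths[["release_b"]]))
  genes_df <- as.data.frame(data.table::fread(paths[["genes"]], header = FALSE))
  colnames(genes_df) <- c("chrom", "start", "end", "gene_id")
  list(predictions = predictions, features = features,
       release_a = release_a, release_b = release_b,
       clstr = readLines(paths[["clstr"]]),
       repeat_text = readLines(paths[["repeats"]]),
       motif_calls = read_motif_bed(paths[["motifs"]]),
       genes = genes_df[, c("gene_id", "chrom", "start", "end")],
       lengths = stats::setNames(release_a$length, release_a$transcript_id))
}

#' Run the full uncertainty-aware benchmarking pipeline
#'
#' Executes the stages in order — simulate (or load), cohort construction,
#' feature extraction, ensemble uncertainty, enrichment, attribution — and
#' writes every declared output plus a JSON run manifest (package version,
#' seeds, config defaults actually used, and an md5 digest per output). A
#' stage failure halts the run with the failing stage named; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("simulate", pipeline_inputs(config, out_dir))

  ## cohort: label-stable set, cluster representatives, folds
  cohort <- stage("cohort", {
    stable <- intersect_releases(inputs$release_a, inputs$release_b)
    reps <- select_cluster_representatives(inputs$clstr, inputs$lengths)
    ids <- intersect(stable, reps)
    biotype <- stats::setNames(inputs$release_a$biotype,
                               inputs$release_a$transcript_id)
    class_of <- ifelse(biotype[ids] == "protein_coding", "coding", "lncRNA")
    ids_by_class <- split(ids, class_of)
    folds <- make_fold_splits(ids_by_class, k = config$k,
                              seed = stage_seed(config$sim$seed, "folds"))
    manifest <- fold_manifest(folds)
    data.table::fwrite(manifest, emit("fold_manifest.tsv"), sep = "\t")
    list(ids = ids, class_of = stats::setNames(class_of, ids), folds = folds)
  })

  ## features: ML set + repeat set + non-B DNA set, one table
  features <- stage("features", {
    rep_mat <- repeat_feature_matrix(inputs$repeat_text,
                                     inputs$lengths[cohort$ids])
    genes <- inputs$genes
    if ("transcript_id" %in% colnames(genes)) {
      genes <- genes[genes$transcript_id %in% cohort$ids, , drop = FALSE]
      gene_for_tx <- stats::setNames(genes$gene_id, genes$transcript_id)
    } else {
      # gene table without transcript mapping: one gene per transcript id
      gene_for_tx <- stats::setNames(genes$gene_id, genes$gene_id)
    }
    nbd_mat <- nbd_feature_matrix(inputs$motif_calls, genes)
    nbd_tx <- nbd_mat[gene_for_tx[cohort$ids], , drop = FALSE]
    rownames(nbd_tx) <- cohort$ids
    ml <- inputs$features
    ml_data <- ml$data[cohort$ids, , drop = FALSE]
    combined <- cbind(ml_data, rep_mat[cohort$ids, , drop = FALSE], nbd_tx)
    meta <- rbind(
      ml$meta,
      data.frame(name = colnames(rep_mat), kind = "continuous",
                 source = "repeat", units = repeat_feature_schema()$units),
      data.frame(name = colnames(nbd_mat), kind = "continuous",
                 source = "nbd", units = nbd_feature_schema()$units))
    ft <- feature_table(combined, meta)
    data.table::fwrite(cbind(transcript_id = rownames(ft$data), ft$data),
                       emit("feature_matrix.tsv"), sep = "\t")
    jsonlite::write_json(ft$meta, emit("feature_matrix.schema.json"),
                         dataframe = "rows")
    ft
  })

  ## uncertainty: entropy decomposition, stratification, agreement, metrics
  uncertainty <- stage("uncertainty", {
    pr <- inputs$predictions
    keep <- intersect(cohort$ids, pr$transcript_id)
    sel <- match(keep, pr$transcript_id)
    compl <- exclude_incomplete(pr$p[sel, , drop = FALSE])
    ids <- rownames(compl$complete)
    refs <- stats::setNames(pr$reference_label[match(ids, pr$transcript_id)], ids)
    prof <- ensemble_profile(compl$complete)
    thresholds <- compute_thresholds(prof, refs, config$q_low, config$q_high)
    groups <- stratify_transcripts(prof, refs, thresholds)
    agree <- agreement_category(pr$label[match(ids, pr$transcript_id), , drop = FALSE],
                                refs)
    metrics <- lapply(colnames(pr$label), function(tool) {
      evaluate_predictions(pr$label[match(ids, pr$transcript_id), tool], refs)
    })
    names(metrics) <- colnames(pr$label)
    profile_out <- cbind(transcript_id = ids, prof,
                         group = as.character(groups),
                         category = as.character(agree$category))
    data.table::fwrite(profile_out, emit("entropy_profiles.tsv"), sep = "\t")
    jsonlite::write_json(thresholds, emit("stratification_thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(metrics, function(m) m[c("balanced_accuracy", "macro_precision",
                                      "macro_recall", "macro_f1")]),
      emit("tool_metrics.json"), auto_unbox = TRUE, digits = NA)
    list(ids = ids, refs = refs, profiles = prof, thresholds = thresholds,
         groups = groups, agreement = agree, metrics = metrics,
         excluded = compl$excluded_ids)
  })

  ## enrichment: preprocess, cluster, representatives, univariate tests
  enrichment <- stage("enrich", {
    ids <- uncertainty$ids
    ft <- feature_table(features$data[ids, , drop = FALSE], features$meta)
    prep <- preprocess_features(ft)
    clustering <- cluster_features(prep$continuous)
    effect <- vapply(colnames(prep$continuous), function(nm) {
      v <- prep$continuous[[nm]]
      lo <- uncertainty$groups == "low"
      hi <- uncertainty$groups == "high"
      if (sum(lo) < 2 || sum(hi) < 2) return(0)
      mannwhitney_vda(v[lo], v[hi])$cVDA
    }, numeric(1))
    reps <- select_feature_representatives(
      clustering, mode = "max_effect", effect = effect,
      forced = intersect(config$forced_representatives,
                         names(clustering$membership)),
      seed = stage_seed(config$sim$seed, "representatives"))
    results <- run_enrichment(prep$continuous, prep$indicators,
                              uncertainty$refs, uncertainty$groups,
                              sig_alpha = config$sig_alpha,
                              effect_threshold = config$effect_threshold,
                              features = reps)
    data.table::fwrite(results, emit("enrichment_results.tsv"), sep = "\t")
    jsonlite::write_json(
      list(chosen_height = clustering$chosen_height,
           n_clusters = clustering$n_clusters,
           grid = clustering$grid, silhouette = clustering$silhouette,
           membership = as.list(clustering$membership),
           representatives = reps),
      emit("feature_clustering.json"), auto_unbox = TRUE, digits = NA)
    list(prep = prep, clustering = clustering, representatives = reps,
         results = results)
  })

  ## attribution: per-fold forests, tree SHAP on strict held-out sets
  attribution <- stage("explain", {
    ids <- uncertainty$ids
    x <- cbind(enrichment$prep$continuous[, enrichment$representatives,
                                          drop = FALSE],
               enrichment$prep$indicators)
    labels <- uncertainty$refs
    folds <- lapply(cohort$folds, function(f) {
      f$train_ids_by_class <- lapply(f$train_ids_by_class, intersect, ids)
      f$test_ids_by_class <- lapply(f$test_ids_by_class, intersect, ids)
      f$heldout_ids_by_class <- lapply(f$heldout_ids_by_class, intersect, ids)
      f
    })
    fits <- train_forests(x, labels, folds, config$forest)
    explanations <- lapply(seq_along(fits$folds), function(i) {
      held <- unlist(folds[[i]]$heldout_ids_by_class, use.names = FALSE)
      explain_forest(fits$folds[[i]], x[held, , drop = FALSE])
    })
    importance <- summarize_importance(explanations)
    data.table::fwrite(importance, emit("global_importance.tsv"), sep = "\t")
    embedding <- NULL
    if (config$run_embedding) {
      emb <- embed_2d(enrichment$prep$continuous,
                      seed = config$sim$seed)
      embedding <- data.frame(transcript_id = rownames(emb), emb)
      data.table::fwrite(embedding, emit("embedding.tsv"), sep = "\t")
    }
    list(fits = fits, explanations = explanations, importance = importance,
         embedding = embedding)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lncentropy")),
    seed = config$sim$seed,
    k = config$k,
    quantiles = c(config$q_low, config$q_high),
    sig_alpha = config$sig_alpha,
    effect_threshold = config$effect_threshold,
    forest = unclass(config$forest),
    n_transcripts = length(uncertainty$ids),
    n_excluded = length(uncertainty$excluded),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, features = features,
                 uncertainty = uncertainty, enrichment = enrichment,
                 attribution = attribution, manifest = manifest))
}
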