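#' Random-forest configuration
#'
#' Hyperparameters for the per-fold classification forests. Defaults: 500
#' trees, sqrt-of-p feature subsampling at each split, minimum leaf size 1,
#' decision threshold 0.5. `recalibrate = TRUE` replaces the threshold per
#' fold by the Youden-J optimum on the training fold's out-of-bag votes.
#'
#' @param n_trees number of trees (>= 1).
#' @param max_features_rule `"sqrt"`, `"log2"` or `"all"`: how many features
#'   are tried at each split.
#' @param min_leaf minimum terminal-node size.
#' @param seed integer seed (each fold derives its own stream).
#' @param decision_threshold probability cutoff for the coding label.
#' @param recalibrate logical; per-fold Youden-J threshold recalibration.
#' @return list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, max_features_rule = c("sqrt", "log2", "all"),
                          min_leaf = 1, seed = 1L, decision_threshold = 0.5,
                          recalibrate = FALSE) {
  max_features_rule <- match.arg(max_features_rule)
  stopifnot(n_trees >= 1, min_leaf >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_features_rule = max_features_rule,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 recalibrate = isTRUE(recalibrate)),
            class = "forest_config")
}

mtry_from_rule <- function(rule, p) {
  switch(rule,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         all = p)
}

#' Train one random forest per cross-validation fold
#'
#' Fits a seeded classification forest on each fold's balanced training set
#' (training ids come from [make_fold_splits()]), keeping the in-bag counts
#' and training matrix needed for probability-space attribution. Out-of-fold
#' explanations must use each transcript's strict held-out fold (see
#' [explain_forest()]); training never sees the held-out ids.
#'
#' @param x data.frame/matrix of features, rows named by transcript id (all
#'   numeric; encode categoricals as indicators first).
#' @param labels named character vector (`coding`/`lncRNA`) covering all ids.
#' @param folds fold list from [make_fold_splits()].
#' @param config a [forest_config()].
#' @return list of class `fold_forests`: per fold, `model` (randomForest),
#'   `train_ids`, `x_train`, `threshold`; plus `config` and `feature_names`.
#' @export
train_forests <- function(x, labels, folds, config = forest_config()) {
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all features must be numeric; one-hot encode categoricals first")
  }
  all_train <- unique(unlist(lapply(folds, function(f) unlist(f$train_ids_by_class))))
  missing <- setdiff(all_train, rownames(x))
  if (length(missing)) {
    stop("features missing for training id(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  missing_lab <- setdiff(all_train, names(labels))
  if (length(missing_lab)) {
    stop("labels missing for training id(s): ",
         paste(utils::head(missing_lab, 3), collapse = ", "))
  }
  fits <- lapply(folds, function(f) {
    train_ids <- unlist(f$train_ids_by_class, use.names = FALSE)
    xt <- x[train_ids, , drop = FALSE]
    yt <- factor(labels[train_ids], levels = c("coding", "lncRNA"))
    model <- with_seed(stage_seed(config$seed + f$fold_index, "forest"),
      randomForest::randomForest(
        x = xt, y = yt, ntree = config$n_trees,
        mtry = mtry_from_rule(config$max_features_rule, ncol(xt)),
        nodesize = config$min_leaf,
        keep.inbag = TRUE, keep.forest = TRUE))
    threshold <- config$decision_threshold
    if (config$recalibrate) {
      oob <- model$votes[, "coding"]
      cand <- sort(unique(oob))
      j <- vapply(cand, function(thr) {
        pred <- ifelse(oob >= thr, "coding", "lncRNA")
        sens <- mean(pred[yt == "coding"] == "coding")
        spec <- mean(pred[yt == "lncRNA"] == "lncRNA")
        sens + spec - 1
      }, numeric(1))
      threshold <- cand[which.max(j)]
    }
    list(model = model, train_ids = train_ids, x_train = xt,
         threshold = threshold, fold_index = f$fold_index)
  })
  structure(list(folds = fits, config = config, feature_names = colnames(x)),
            class = "fold_forests")
}

# Flatten a randomForest into the node arrays the C++ kernel expects.
# Children/feature indices 0-based; children -1 at leaves; leaf value 1 for
# the "coding" vote, 0 otherwise.
flatten_forest <- function(model) {
  n_trees <- model$ntree
  lefts <- rights <- svars <- list()
  spoints <- values <- list()
  offsets <- integer(n_trees + 1)
  coding_level <- which(levels(model$y) == "coding")
  for (t in seq_len(n_trees)) {
    tr <- randomForest::getTree(model, t, labelVar = FALSE)
    is_leaf <- tr[, "status"] == -1
    lefts[[t]] <- as.integer(ifelse(is_leaf, -1L, tr[, "left daughter"] - 1L))
    rights[[t]] <- as.integer(ifelse(is_leaf, -1L, tr[, "right daughter"] - 1L))
    svars[[t]] <- as.integer(ifelse(is_leaf, 0L, tr[, "split var"] - 1L))
    spoints[[t]] <- ifelse(is_leaf, 0, tr[, "split point"])
    values[[t]] <- ifelse(is_leaf & tr[, "prediction"] == coding_level, 1, 0)
    offsets[t + 1] <- offsets[t] + nrow(tr)
  }
  list(left = unlist(lefts), right = unlist(rights), svar = unlist(svars),
       spoint = unlist(spoints), leaf_value = unlist(values),
       tree_offset = offsets)
}

#' Per-transcript additive feature attributions (tree SHAP)
#'
#' Computes exact path-dependent Shapley values for each explained
#' transcript against the forest's probability output. Because each tree
#' contributes its leaf vote and the forest probability is the mean vote,
#' the attributions are expressed directly in probability units:
#' `baseline + sum(phi) = f(x)` for every transcript, where the baseline is
#' the in-bag expected predicted probability. Additivity is checked to
#' `1e-6` and violations are an error.
#'
#' @param fit one element of `train_forests()$folds` (or a list with
#'   `model` and `x_train`).
#' @param newdata data.frame/matrix of transcripts to explain (same feature
#'   schema as training; typically the fold's strict held-out set).
#' @return list of class `transcript_explanations`: `baseline` (scalar),
#'   `phi` (n x p matrix), `prediction` (numeric, forest coding
#'   probability), `ids`.
#' @export
explain_forest <- function(fit, newdata) {
  model <- fit$model
  newdata <- as.data.frame(newdata)
  schema <- colnames(fit$x_train)
  if (!identical(colnames(newdata), schema)) {
    stop("feature schema mismatch between training data and newdata")
  }
  flat <- flatten_forest(model)
  res <- forest_shap_cpp(
    flat$left, flat$right, flat$svar, flat$spoint, flat$leaf_value,
    flat$tree_offset,
    as.matrix(fit$x_train),
    matrix(as.numeric(model$inbag), nrow(fit$x_train), model$ntree),
    as.matrix(newdata))
  colnames(res$phi) <- schema
  gap <- abs(res$baseline + rowSums(res$phi) - res$fx)
  if (any(gap > 1e-6)) {
    stop(sprintf("additivity violated: max |baseline + sum(phi) - f(x)| = %.3g",
                 max(gap)))
  }
  structure(list(baseline = res$baseline, phi = res$phi,
                 prediction = res$fx, ids = rownames(newdata)),
            class = "transcript_explanations")
}

#' Top-k view of one transcript's explanation
#'
#' The waterfall view: the k largest-|phi| features individually, all
#' remaining features aggregated into one remainder term, so that
#' `baseline + sum(shown) + remainder = prediction`.
#'
#' @param explanation a [explain_forest()] result.
#' @param i transcript index or id.
#' @param k number of features shown individually (default 10).
#' @return list with `baseline`, `prediction`, `top` (named numeric,
#'   decreasing |phi|), `remainder` (scalar), `n_aggregated`.
#' @export
top_contributions <- function(explanation, i, k = 10) {
  if (is.character(i)) i <- match(i, explanation$ids)
  phi <- explanation$phi[i, ]
  ord <- order(-abs(phi))
  top <- phi[ord[seq_len(min(k, length(phi)))]]
  rest <- if (length(phi) > k) sum(phi[ord[-seq_len(k)]]) else 0
  list(baseline = explanation$baseline,
       prediction = explanation$prediction[i],
       top = top, remainder = rest,
       n_aggregated = max(0L, length(phi) - k))
}

#' Global feature importance from per-fold explanations
#'
#' Pools the out-of-fold attributions of all folds: global importance is the
#' mean absolute Shapley value per feature over all explained transcripts;
#' stability is the standard deviation of the per-fold means; features are
#' ranked by decreasing importance.
#'
#' @param explanations list of [explain_forest()] results (one per fold).
#' @return data.frame with `feature`, `mean_abs_shap`, `sd_across_folds`,
#'   `rank`, ordered by rank.
#' @export
summarize_importance <- function(explanations) {
  stopifnot(length(explanations) >= 1)
  per_fold <- vapply(explanations, function(e) colMeans(abs(e$phi)),
                     numeric(ncol(explanations[[1]]$phi)))
  per_fold <- matrix(per_fold, ncol = length(explanations),
                     dimnames = list(colnames(explanations[[1]]$phi), NULL))
  pooled_abs <- do.call(rbind, lapply(explanations, function(e) abs(e$phi)))
  mean_abs <- colMeans(pooled_abs)
  sd_folds <- apply(per_fold, 1, function(r)
    if (length(r) > 1) stats::sd(r) else 0)
  out <- data.frame(feature = names(mean_abs),
                    mean_abs_shap = unname(mean_abs),
                    sd_across_folds = unname(sd_folds[names(mean_abs)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
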