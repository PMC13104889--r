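#' Binary Shannon entropy (base 2)
#'
#' Entropy of a Bernoulli probability, the building block of the ensemble
#' uncertainty decomposition: `H(p) = -[p log2 p + (1-p) log2(1-p)]`, with the
#' convention `0 * log2(0) = 0` so that `H(0) = H(1) = 0` and `H(0.5) = 1`.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of entropies in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("'p' must be numeric probabilities in [0, 1]")
  }
  term <- function(q) ifelse(q == 0, 0, q * log2(q))
  -(term(p) + term(1 - p)) + 0  # "+ 0" normalizes IEEE -0 at the extremes
}

#' Orient a raw classifier score to a coding probability
#'
#' Classifiers differ in which class they score as positive. Tools whose
#' positive class is the lncRNA class have their score inverted so that every
#' tool reports a probability of the transcript being protein-coding. The
#' decision threshold is oriented alongside the score; the label is coding
#' iff `p_coding >= oriented threshold` (ties resolve to coding).
#'
#' @param raw_score numeric vector of raw scores in `[0, 1]`.
#' @param positive_class `"coding"` or `"lncRNA"`: the class the raw score is
#'   the probability of.
#' @param threshold decision threshold on the raw score (default 0.5).
#' @param ids optional transcript ids used in error messages.
#' @return a list with `p_coding` (numeric) and `label` (character,
#'   `"coding"`/`"lncRNA"`).
#' @examples
#' orient_scores(0.3, positive_class = "lncRNA")  # p_coding 0.7
#' @export
orient_scores <- function(raw_score, positive_class = c("coding", "lncRNA"),
                          threshold = 0.5, ids = NULL) {
  positive_class <- match.arg(positive_class)
  bad <- which(!is.finite(raw_score) | raw_score < 0 | raw_score > 1)
  if (length(bad)) {
    id <- if (!is.null(ids)) ids[bad[1]] else bad[1]
    stop(sprintf("raw score outside [0, 1] for transcript '%s' (positive class %s)",
                 id, positive_class))
  }
  if (positive_class == "coding") {
    p <- raw_score
    thr <- threshold
  } else {
    p <- 1 - raw_score
    thr <- 1 - threshold
  }
  list(p_coding = p, label = ifelse(p >= thr, "coding", "lncRNA"))
}

#' Ensemble entropy decomposition
#'
#' Given per-tool coding probabilities for a set of transcripts, computes the
#' uncertainty decomposition of the M-tool ensemble:
#' \itemize{
#'   \item `p_mean`: arithmetic mean coding probability across tools;
#'   \item `H_pred`: predictive entropy, [binary_entropy()] of `p_mean`;
#'   \item `H_exp`: expected entropy, mean of the per-tool entropies;
#'   \item `I_dis`: disagreement score `H_pred - H_exp`, the mutual-information
#'     component; nonnegative by concavity of the entropy, zero iff all tools
#'     agree exactly, and maximal (1 bit) when confident tools split evenly.
#' }
#'
#' @param p matrix (or data.frame) of coding probabilities, one row per
#'   transcript and one column per tool; `M >= 2` columns, no missing values
#'   (exclude incomplete transcripts first, see [exclude_incomplete()]).
#' @return data.frame with columns `p_mean`, `H_pred`, `H_exp`, `I_dis`
#'   (row names preserved from `p`).
#' @examples
#' ensemble_profile(rbind(c(0.8, 0.6), c(1, 0)))
#' @export
ensemble_profile <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) < 2) stop("ensemble needs M >= 2 tools")
  if (anyNA(p)) stop("missing tool probabilities; run exclude_incomplete() first")
  p_mean <- rowMeans(p)
  h_pred <- binary_entropy(p_mean)
  h_exp <- rowMeans(matrix(binary_entropy(as.vector(p)), nrow = nrow(p)))
  data.frame(
    p_mean = p_mean, H_pred = h_pred, H_exp = h_exp,
    I_dis = h_pred - h_exp,
    row.names = rownames(p)
  )
}

#' Drop transcripts not scored by every tool
#'
#' Some tools cannot score every transcript (length limits, missing ORF,
#' non-canonical nucleotides). Downstream ensemble statistics require all M
#' probabilities, so transcripts with any missing tool score are excluded and
#' reported.
#'
#' @param p matrix/data.frame of per-tool coding probabilities (rows named by
#'   transcript).
#' @return list with `complete` (the retained submatrix), `excluded_ids`,
#'   and `per_tool_missing` (named integer vector of missing counts by tool).
#' @export
exclude_incomplete <- function(p) {
  p <- as.matrix(p)
  miss <- is.na(p)
  keep <- rowSums(miss) == 0
  list(
    complete = p[keep, , drop = FALSE],
    excluded_ids = rownames(p)[!keep],
    per_tool_missing = colSums(miss)
  )
}

#' Per-class percentile thresholds for uncertainty stratification
#'
#' Splits transcripts by reference class and computes, within each class, the
#' 10th and 90th percentiles of predictive entropy and the 90th percentile of
#' the disagreement score. Percentiles use linear interpolation over order
#' statistics (the interpolated index is `q * (N - 1)`, zero-based;
#' `stats::quantile()` type 7), the convention that reproduces the published
#' low-entropy group sizes from the class counts.
#'
#' @param profiles data.frame from [ensemble_profile()] (columns `H_pred`,
#'   `I_dis`).
#' @param labels character/factor vector of reference classes, parallel to
#'   `profiles` rows.
#' @param q_low,q_high quantile probabilities (defaults 0.10 and 0.90).
#' @return named list, one element per class, each with `q10_Hpred`,
#'   `q90_Hpred`, `q90_Idis`; carries attribute
#'   `quantile_convention = "linear_order_statistics_type7"`.
#' @export
compute_thresholds <- function(profiles, labels, q_low = 0.10, q_high = 0.90) {
  stopifnot(nrow(profiles) == length(labels))
  labels <- as.character(labels)
  out <- lapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) < 10) {
      stop("fewer than 10 transcripts in a reference class; cannot compute percentiles")
    }
    h <- profiles$H_pred[idx]
    d <- profiles$I_dis[idx]
    list(
      q10_Hpred = unname(stats::quantile(h, q_low, type = 7)),
      q90_Hpred = unname(stats::quantile(h, q_high, type = 7)),
      q90_Idis = unname(stats::quantile(d, q_high, type = 7))
    )
  })
  attr(out, "quantile_convention") <- "linear_order_statistics_type7"
  out
}

#' Stratify transcripts into uncertainty groups
#'
#' Applies the per-class percentile rule: a transcript is `low` entropy iff
#' `H_pred` is strictly below its class's 10th percentile, `high` entropy iff
#' both `H_pred` and `I_dis` are strictly above their class's 90th
#' percentiles, and `intermediate` otherwise. Inequalities are strict, so a
#' transcript exactly at a threshold is intermediate.
#'
#' @param profiles data.frame from [ensemble_profile()].
#' @param labels reference class per transcript.
#' @param thresholds output of [compute_thresholds()] for the same population.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
stratify_transcripts <- function(profiles, labels, thresholds) {
  stopifnot(nrow(profiles) == length(labels))
  labels <- as.character(labels)
  if (!all(unique(labels) %in% names(thresholds))) {
    stop("thresholds missing for some reference class")
  }
  q10 <- vapply(thresholds, `[[`, numeric(1), "q10_Hpred")[labels]
  q90h <- vapply(thresholds, `[[`, numeric(1), "q90_Hpred")[labels]
  q90i <- vapply(thresholds, `[[`, numeric(1), "q90_Idis")[labels]
  grp <- rep("intermediate", length(labels))
  grp[profiles$H_pred < q10] <- "low"
  grp[profiles$H_pred > q90h & profiles$I_dis > q90i] <- "high"
  factor(grp, levels = c("low", "intermediate", "high"))
}

#' Categorize inter-tool agreement
#'
#' For each transcript, counts tools whose label matches the reference and
#' assigns one of three categories: `unanimous_correct` (all M match),
#' `unanimous_incorrect` (none match), and `discordant` otherwise.
#' `near_consensus` flags transcripts where only one or two tools dissent
#' (`n_correct` in `{M-1, M-2}`). The voting `pattern` (which tools predicted
#' coding) supports upset-style summaries.
#'
#' @param labels matrix/data.frame of per-tool labels (`"coding"`/`"lncRNA"`),
#'   one row per transcript.
#' @param reference character vector of reference labels.
#' @return data.frame with `n_correct`, `category`, `near_consensus`,
#'   `pattern` (comma-separated tool names voting coding).
#' @export
agreement_category <- function(labels, reference) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(reference))
  m <- ncol(labels)
  correct <- labels == matrix(reference, nrow(labels), m)
  n_correct <- rowSums(correct)
  category <- ifelse(n_correct == m, "unanimous_correct",
              ifelse(n_correct == 0, "unanimous_incorrect", "discordant"))
  tools <- colnames(labels)
  if (is.null(tools)) tools <- paste0("tool", seq_len(m))
  pattern <- apply(labels == "coding", 1, function(v) paste(tools[v], collapse = ","))
  data.frame(
    n_correct = n_correct,
    category = factor(category,
                      levels = c("unanimous_correct", "discordant", "unanimous_incorrect")),
    near_consensus = n_correct >= m - 2 & n_correct <= m - 1,
    pattern = pattern,
    row.names = rownames(labels)
  )
}

#' Macro-averaged classification metrics
#'
#' Evaluates binary predictions against reference labels with the metrics
#' appropriate for class-imbalanced benchmarks: balanced accuracy (mean of
#' per-class recalls) and macro-averaged precision, recall and F1
#' (unweighted means over the two classes). Per-class F1 is the harmonic mean
#' of that class's precision and recall. A class with zero predicted
#' positives gets precision 0 and is flagged.
#'
#' @param predicted character vector of predicted labels.
#' @param reference character vector of reference labels (both classes must
#'   be present).
#' @param classes the two class labels; defaults to `c("coding", "lncRNA")`.
#' @return list with `balanced_accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `confusion` (2x2 table, reference x predicted), `per_class`
#'   data.frame, and `zero_prediction_classes`.
#' @export
evaluate_predictions <- function(predicted, reference,
                                 classes = c("coding", "lncRNA")) {
  stopifnot(length(predicted) == length(reference))
  if (!all(classes %in% reference)) {
    stop("both classes must be present in the reference labels")
  }
  confusion <- table(
    reference = factor(reference, levels = classes),
    predicted = factor(predicted, levels = classes)
  )
  per_class <- lapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    recall <- tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               predicted_positives = tp + fp)
  })
  per_class <- do.call(rbind, per_class)
  list(
    balanced_accuracy = mean(per_class$recall),
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1),
    confusion = confusion,
    per_class = per_class,
    zero_prediction_classes = per_class$class[per_class$predicted_positives == 0]
  )
}
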