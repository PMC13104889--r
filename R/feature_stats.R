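#' Construct a feature table
#'
#' A feature table couples a transcripts-by-features data.frame with
#' per-feature metadata: `kind` (`continuous`/`categorical`), `source`
#' (`ml_tool`, `repeat`, `nbd`) and `units`. Feature names must be unique.
#'
#' @param data data.frame, rows named by transcript id.
#' @param meta data.frame with columns `name`, `kind`, `source`, `units`;
#'   one row per column of `data`, in order. Missing metadata are inferred
#'   (`kind` from column type, `source = "ml_tool"`, empty units).
#' @return object of class `feature_table` (list with `data` and `meta`).
#' @export
feature_table <- function(data, meta = NULL) {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(colnames(data))) stop("duplicate feature names")
  if (is.null(meta)) {
    meta <- data.frame(
      name = colnames(data),
      kind = ifelse(vapply(data, is.numeric, logical(1)), "continuous", "categorical"),
      source = "ml_tool",
      units = "",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(identical(meta$name, colnames(data)),
            all(meta$kind %in% c("continuous", "categorical")))
  structure(list(data = data, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d transcripts x %d features (%d continuous, %d categorical)\n",
              nrow(x$data), ncol(x$data),
              sum(x$meta$kind == "continuous"), sum(x$meta$kind == "categorical")))
  invisible(x)
}

#' Preprocess a feature table for statistical analysis
#'
#' Applies the standard preprocessing sequence: constant features (one value
#' across all transcripts, missing values ignored) and all-missing features
#' are dropped and reported; categorical features are expanded to one binary
#' indicator per level (no reference level dropped); continuous features pass
#' through unchanged.
#'
#' @param ft a [feature_table()].
#' @return list with `continuous` (data.frame), `indicators` (data.frame of
#'   0/1 columns named `feature=level`), and `dropped` (data.frame of feature
#'   name + reason).
#' @export
preprocess_features <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  dropped <- data.frame(name = character(), reason = character())
  keep_cont <- list()
  keep_ind <- list()
  for (i in seq_len(ncol(ft$data))) {
    nm <- ft$meta$name[i]
    v <- ft$data[[i]]
    vv <- v[!is.na(v)]
    if (length(vv) == 0) {
      dropped <- rbind(dropped, data.frame(name = nm, reason = "all_missing"))
      next
    }
    if (length(unique(vv)) == 1) {
      dropped <- rbind(dropped, data.frame(name = nm, reason = "constant"))
      next
    }
    if (ft$meta$kind[i] == "continuous") {
      keep_cont[[nm]] <- v
    } else {
      for (lev in sort(unique(as.character(vv)))) {
        keep_ind[[paste0(nm, "=", lev)]] <- as.integer(as.character(v) == lev)
      }
    }
  }
  mk <- function(l) {
    if (length(l) == 0) {
      d <- data.frame(row.names = rownames(ft$data))
    } else {
      d <- data.frame(l, row.names = rownames(ft$data), check.names = FALSE)
    }
    d
  }
  list(continuous = mk(keep_cont), indicators = mk(keep_ind), dropped = dropped)
}

#' Cluster redundant continuous features
#'
#' Features that encode the same signal (e.g. length in nt and in kb, or
#' correlated k-mer scores) are grouped so that enrichment tests are run on
#' one representative per group. Pairwise Spearman correlation gives the
#' distance `d = 1 - |rho|` (anti-correlated features are equally redundant);
#' Ward linkage builds the tree; the cut height is chosen by maximizing the
#' mean silhouette width (computed on `d`) over a grid of evenly spaced
#' heights between the smallest and largest merge heights, considering only
#' cuts that yield at least 2 clusters. Ties prefer fewer clusters.
#'
#' @param x data.frame/matrix of continuous features (columns are features).
#' @param n_grid number of cut heights to scan (default 25).
#' @return object of class `feature_clustering`: list with `tree` (hclust),
#'   `grid`, `silhouette` (mean width per grid point, NA where < 2 clusters),
#'   `chosen_height`, `membership` (named integer vector), `n_clusters`.
#'   With fewer than 3 features a single cluster is returned with a warning.
#' @export
cluster_features <- function(x, n_grid = 25) {
  x <- as.data.frame(x)
  feats <- colnames(x)
  if (ncol(x) < 3) {
    warning("fewer than 3 continuous features; returning a single cluster")
    membership <- stats::setNames(rep(1L, ncol(x)), feats)
    return(structure(list(tree = NULL, grid = numeric(), silhouette = numeric(),
                          chosen_height = NA_real_, membership = membership,
                          n_clusters = 1L),
                     class = "feature_clustering"))
  }
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  dd <- stats::as.dist(d)
  tree <- stats::hclust(dd, method = "ward.D2")
  grid <- seq(min(tree$height), max(tree$height), length.out = n_grid)
  sil <- rep(NA_real_, n_grid)
  members <- vector("list", n_grid)
  for (i in seq_along(grid)) {
    cl <- stats::cutree(tree, h = grid[i])
    members[[i]] <- cl
    if (length(unique(cl)) >= 2 && length(unique(cl)) < ncol(x)) {
      sw <- cluster::silhouette(cl, dd)
      sil[i] <- mean(sw[, "sil_width"])
    } else if (length(unique(cl)) == ncol(x)) {
      # all-singleton cut: silhouette undefined; treat each point's width as 0
      sil[i] <- 0
    }
  }
  if (all(is.na(sil))) {
    best <- 1L
  } else {
    cand <- which(sil == max(sil, na.rm = TRUE))
    # ties: fewer clusters
    ncl <- vapply(members[cand], function(m) length(unique(m)), integer(1))
    best <- cand[which.min(ncl)]
  }
  membership <- members[[best]]
  names(membership) <- feats
  structure(list(tree = tree, grid = grid, silhouette = sil,
                 chosen_height = grid[best], membership = membership,
                 n_clusters = length(unique(membership))),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("feature_clustering: %d features in %d clusters (cut height %.4g)\n",
              length(x$membership), x$n_clusters, x$chosen_height))
  invisible(x)
}

#' Select one representative feature per cluster
#'
#' For each cluster either the feature with the largest absolute effect size
#' (`mode = "max_effect"`; ties broken by lexicographically smallest name) or
#' a seeded uniform random member (`mode = "random"`) is retained. Features
#' in `forced` always win their cluster (e.g. transcript length, kept for its
#' documented relevance regardless of effect size); two forced features in
#' one cluster is an error.
#'
#' @param clustering a [cluster_features()] result.
#' @param mode `"max_effect"` or `"random"`.
#' @param effect named numeric vector of effect sizes (required for
#'   `max_effect`).
#' @param forced character vector of feature names to force as
#'   representatives.
#' @param seed integer seed for `mode = "random"`.
#' @return character vector of representative feature names (one per
#'   cluster, ordered by cluster id).
#' @export
select_feature_representatives <- function(clustering,
                                           mode = c("max_effect", "random"),
                                           effect = NULL, forced = character(),
                                           seed = 1L) {
  mode <- match.arg(mode)
  membership <- clustering$membership
  if (mode == "max_effect" && is.null(effect)) {
    stop("mode 'max_effect' requires an 'effect' vector")
  }
  unknown <- setdiff(forced, names(membership))
  if (length(unknown)) stop("forced features not in clustering: ",
                            paste(unknown, collapse = ", "))
  with_seed(seed, {
    reps <- character(0)
    for (cl in sort(unique(membership))) {
      members <- sort(names(membership)[membership == cl])
      f <- intersect(forced, members)
      if (length(f) > 1) {
        stop("two forced features in one cluster: ", paste(f, collapse = ", "))
      }
      if (length(f) == 1) {
        reps <- c(reps, f)
      } else if (mode == "max_effect") {
        e <- abs(effect[members])
        if (anyNA(e)) stop("missing effect size for: ",
                           paste(members[is.na(e)], collapse = ", "))
        reps <- c(reps, members[which.max(e)])  # members sorted: ties lexicographic
      } else {
        reps <- c(reps, if (length(members) == 1) members else sample(members, 1))
      }
    }
    reps
  })
}

#' Mann-Whitney U test with Vargha-Delaney A effect size
#'
#' The Vargha-Delaney A statistic is the probability that a random value
#' from `x` exceeds a random value from `y`, counting ties as 1/2:
#' `A = (#\{x > y\} + 0.5 #\{x = y\}) / (n_x n_y)`, computed via the rank-sum
#' identity `A = (R_x - n_x(n_x+1)/2) / (n_x n_y)`. The centered effect
#' `cVDA = A - 0.5` is 0 under no effect and +/-0.5 under complete
#' separation. The two-sided p-value uses the exact Wilcoxon null
#' distribution when `n_x * n_y <= 400` and there are no ties, and the
#' normal approximation with tie correction otherwise (no continuity
#' correction).
#'
#' @param x,y numeric samples (both nonempty).
#' @return list with `U` (Mann-Whitney statistic for `x`), `p` (two-sided),
#'   `A`, `cVDA`, and `method`.
#' @examples
#' mannwhitney_vda(c(4, 5, 6), c(1, 2, 3))  # cVDA = 0.5
#' @export
mannwhitney_vda <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  u <- rx - nx * (nx + 1) / 2
  a <- u / (nx * ny)
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && nx * ny <= 400) {
    # exact null distribution of U (tie-free)
    p <- 2 * min(stats::pwilcox(u, nx, ny), 1 - stats::pwilcox(u - 1, nx, ny))
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_tie_corrected"
  }
  list(U = u, p = p, A = a, cVDA = a - 0.5, method = method)
}

#' Chi-squared test of independence with Cramer's V and odds ratio
#'
#' Pearson chi-squared without continuity correction (one formula across
#' table shapes); effect size `V = sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#' For 2x2 tables the odds ratio `ad/bc` is returned, with the Haldane
#' correction (+0.5 on every cell) when any cell is zero.
#'
#' @param tab matrix of nonnegative integer counts (2 x K); all row and
#'   column margins must be positive.
#' @return list with `chi2`, `df`, `p`, `V`, and `OR` (NA unless 2x2).
#' @examples
#' chisq_cramers(rbind(c(30, 10), c(10, 30)))  # chi2 = 20, V = 0.5, OR = 9
#' @export
chisq_cramers <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  v <- sqrt(chi2 / (n * min(nrow(tab) - 1, ncol(tab) - 1)))
  or <- NA_real_
  if (all(dim(tab) == c(2, 2))) {
    t2 <- tab
    if (any(t2 == 0)) t2 <- t2 + 0.5
    or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  }
  list(chi2 = chi2, df = df, p = p, V = v, OR = or)
}

#' Benjamini-Hochberg adjustment
#'
#' Validates that the inputs are probabilities and applies the standard
#' step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (NAs propagated).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Univariate enrichment of features across transcript groups
#'
#' Runs, for each feature and each requested comparison, the test matched to
#' the feature kind: Mann-Whitney U with centered Vargha-Delaney A for
#' continuous features, chi-squared with Cramer's V and odds ratio for
#' binary/categorical indicator features. P-values are BH-adjusted within
#' each comparison family. A result is `significant` iff adjusted p is below
#' `sig_alpha` and `non_negligible` iff `|cVDA|` (continuous) or `V`
#' (categorical) exceeds `effect_threshold`. `direction` reports which group
#' carries the larger values (continuous: sign of cVDA; categorical: OR vs 1).
#'
#' Comparisons are defined on two group labellings: the entropy groups
#' (`low_vs_high` compares low- vs high-entropy transcripts) and the
#' reference classes within an entropy group (`lnc_vs_pc_low`,
#' `lnc_vs_pc_high`). In every comparison the first named group is the
#' "positive" side of the effect.
#'
#' @param continuous data.frame of continuous features (possibly empty).
#' @param indicators data.frame of 0/1 indicator features (possibly empty).
#' @param class_labels reference class per transcript (`coding`/`lncRNA`).
#' @param entropy_groups factor per transcript (`low`/`intermediate`/`high`).
#' @param comparisons subset of
#'   `c("low_vs_high", "lnc_vs_pc_low", "lnc_vs_pc_high")`.
#' @param sig_alpha adjusted-p significance threshold (default 0.01).
#' @param effect_threshold non-negligible effect-size threshold (default 0.1;
#'   0.15 is the stricter alternative used in some summaries).
#' @param features optional character vector restricting continuous features
#'   (e.g. cluster representatives); indicators are always all tested.
#' @return data.frame, one row per feature x comparison, with columns
#'   `feature`, `comparison`, `test`, `statistic`, `p_raw`, `p_adj`,
#'   `effect`, `odds_ratio`, `direction`, `significant`, `non_negligible`.
#'   Comparisons where either group has fewer than 2 members are skipped and
#'   recorded in attribute `skipped`.
#' @export
run_enrichment <- function(continuous, indicators, class_labels, entropy_groups,
                           comparisons = c("low_vs_high", "lnc_vs_pc_low",
                                           "lnc_vs_pc_high"),
                           sig_alpha = 0.01, effect_threshold = 0.1,
                           features = NULL) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  class_labels <- as.character(class_labels)
  entropy_groups <- as.character(entropy_groups)
  if (!is.null(features)) {
    continuous <- continuous[, intersect(features, colnames(continuous)), drop = FALSE]
  }
  group_masks <- function(comp) {
    switch(comp,
      low_vs_high = list(a = entropy_groups == "low", b = entropy_groups == "high"),
      lnc_vs_pc_low = list(a = class_labels == "lncRNA" & entropy_groups == "low",
                           b = class_labels == "coding" & entropy_groups == "low"),
      lnc_vs_pc_high = list(a = class_labels == "lncRNA" & entropy_groups == "high",
                            b = class_labels == "coding" & entropy_groups == "high"))
  }
  rows <- list()
  skipped <- character(0)
  for (comp in comparisons) {
    gm <- group_masks(comp)
    if (sum(gm$a) < 2 || sum(gm$b) < 2) {
      skipped <- c(skipped, comp)
      next
    }
    comp_rows <- list()
    for (nm in colnames(continuous)) {
      v <- continuous[[nm]]
      res <- mannwhitney_vda(v[gm$a], v[gm$b])
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        feature = nm, comparison = comp, test = "mann_whitney",
        statistic = res$U, p_raw = res$p, effect = res$cVDA,
        odds_ratio = NA_real_,
        direction = if (res$cVDA > 0) "first" else if (res$cVDA < 0) "second" else "none")
    }
    for (nm in colnames(indicators)) {
      v <- indicators[[nm]]
      tab <- rbind(c(sum(v[gm$a] == 1, na.rm = TRUE), sum(v[gm$a] == 0, na.rm = TRUE)),
                   c(sum(v[gm$b] == 1, na.rm = TRUE), sum(v[gm$b] == 0, na.rm = TRUE)))
      if (any(colSums(tab) == 0)) next  # indicator constant within this comparison
      res <- chisq_cramers(tab)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        feature = nm, comparison = comp, test = "chi_squared",
        statistic = res$chi2, p_raw = res$p, effect = res$V,
        odds_ratio = res$OR,
        direction = if (is.na(res$OR) || res$OR == 1) "none"
                    else if (res$OR > 1) "first" else "second")
    }
    if (!length(comp_rows)) next
    block <- do.call(rbind, comp_rows)
    block$p_adj <- bh_adjust(block$p_raw)
    rows[[comp]] <- block
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), comparison = character(), test = character(),
               statistic = numeric(), p_raw = numeric(), effect = numeric(),
               odds_ratio = numeric(), direction = character(), p_adj = numeric())
  rownames(out) <- NULL
  out$significant <- out$p_adj < sig_alpha
  out$non_negligible <- abs(out$effect) > effect_threshold
  attr(out, "skipped") <- skipped
  out
}
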