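# shared fixture: a small two-class problem with one strong feature
forest_fixture <- function(n = 300, p = 5, informative = 1, shift = 2,
                           seed = 1, k = 2) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- sprintf("T%04d", seq_len(n))
  cls <- rep(c("coding", "lncRNA"), length.out = n)
  for (j in seq_len(informative)) {
    x[[j]] <- x[[j]] + ifelse(cls == "coding", shift, -shift)
  }
  labels <- stats::setNames(cls, rownames(x))
  folds <- make_fold_splits(split(rownames(x), cls), k = k, seed = seed)
  list(x = x, labels = labels, folds = folds)
}

test_that("training is deterministic and a separable feature is learned", {
  fx <- forest_fixture(n = 200, shift = 6)
  cfg <- forest_config(n_trees = 100, seed = 3)
  fit1 <- train_forests(fx$x, fx$labels, fx$folds, cfg)
  fit2 <- train_forests(fx$x, fx$labels, fx$folds, cfg)
  held <- unlist(fx$folds[[1]]$heldout_ids_by_class)
  p1 <- predict(fit1$folds[[1]]$model, fx$x[held, ], type = "prob")[, "coding"]
  p2 <- predict(fit2$folds[[1]]$model, fx$x[held, ], type = "prob")[, "coding"]
  expect_identical(p1, p2)
  # near-perfect held-out accuracy in the separable limit
  pred <- ifelse(p1 >= 0.5, "coding", "lncRNA")
  m <- evaluate_predictions(pred, fx$labels[held])
  expect_gte(m$balanced_accuracy, 0.97)
  # id/feature mismatches are reported
  expect_error(train_forests(fx$x[-1, ], fx$labels, fx$folds, cfg), "missing")
})

test_that("permuted labels give chance-level held-out accuracy", {
  accs <- vapply(1:20, function(s) {
    fx <- forest_fixture(n = 160, shift = 2, seed = 100 + s)
    perm <- with_seed_fixture(s, sample(fx$labels))
    names(perm) <- names(fx$labels)
    folds <- make_fold_splits(split(names(perm), perm), k = 2, seed = s)
    fit <- train_forests(fx$x, perm, folds, forest_config(n_trees = 60, seed = s))
    held <- unlist(folds[[1]]$heldout_ids_by_class)
    p <- predict(fit$folds[[1]]$model, fx$x[held, ], type = "prob")[, "coding"]
    evaluate_predictions(ifelse(p >= 0.5, "coding", "lncRNA"),
                         perm[held])$balanced_accuracy
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.1)
})

test_that("attributions are additive in probability space and match the forest", {
  fx <- forest_fixture(n = 240, shift = 1.5)
  fit <- train_forests(fx$x, fx$labels, fx$folds, forest_config(n_trees = 80, seed = 7))
  held <- unlist(fx$folds[[1]]$heldout_ids_by_class)
  ex <- explain_forest(fit$folds[[1]], fx$x[held, ])
  gap <- abs(ex$baseline + rowSums(ex$phi) - ex$prediction)
  expect_lt(max(gap), 1e-6)
  # f(x) equals the forest's vote-fraction probability
  p <- predict(fit$folds[[1]]$model, fx$x[held, ], type = "prob")[, "coding"]
  expect_equal(unname(ex$prediction), unname(p))
  # schema mismatch is an error
  xbad <- fx$x[held, rev(colnames(fx$x))]
  expect_error(explain_forest(fit$folds[[1]], xbad), "schema")
})

test_that("a constant feature receives exactly zero attribution", {
  fx <- forest_fixture(n = 160, shift = 2)
  fx$x$const <- 1
  folds <- fx$folds
  fit <- train_forests(fx$x, fx$labels, folds, forest_config(n_trees = 50, seed = 2))
  held <- unlist(folds[[1]]$heldout_ids_by_class)
  ex <- explain_forest(fit$folds[[1]], fx$x[held, ])
  expect_true(all(ex$phi[, "const"] == 0))
})

test_that("the informative feature dominates attribution", {
  fx <- forest_fixture(n = 600, p = 7, informative = 1, shift = 2, seed = 5)
  fit <- train_forests(fx$x, fx$labels, fx$folds,
                       forest_config(n_trees = 300, min_leaf = 10, seed = 5))
  exps <- lapply(seq_along(fit$folds), function(i) {
    held <- unlist(fx$folds[[i]]$heldout_ids_by_class)
    explain_forest(fit$folds[[i]], fx$x[held, ])
  })
  imp <- summarize_importance(exps)
  expect_identical(imp$feature[1], "f1")
  # per-transcript dominance: |phi_f1| exceeds every noise feature's for >= 99%
  dominance <- vapply(exps, function(e) {
    mean(apply(e$phi, 1, function(r) abs(r["f1"]) > max(abs(r[-1]))))
  }, numeric(1))
  expect_gte(mean(dominance), 0.99)
  # noise features sit far below the informative one (>= 5x)
  expect_gte(imp$mean_abs_shap[1], 5 * max(imp$mean_abs_shap[-1]))
})

test_that("duplicated feature columns share attribution symmetrically", {
  fx <- forest_fixture(n = 300, p = 4, shift = 1.5, seed = 9)
  fx$x$f1dup <- fx$x$f1
  fit <- train_forests(fx$x, fx$labels, fx$folds,
                       forest_config(n_trees = 400, min_leaf = 5, seed = 9))
  held <- unlist(fx$folds[[1]]$heldout_ids_by_class)
  ex <- explain_forest(fit$folds[[1]], fx$x[held, ])
  a <- mean(abs(ex$phi[, "f1"])); b <- mean(abs(ex$phi[, "f1dup"]))
  expect_lt(abs(a - b) / (a + b), 0.2)
})

test_that("importance summaries aggregate per-fold explanations", {
  fx <- forest_fixture(n = 200, shift = 2)
  fit <- train_forests(fx$x, fx$labels, fx$folds, forest_config(n_trees = 60, seed = 4))
  held <- unlist(fx$folds[[1]]$heldout_ids_by_class)
  ex <- explain_forest(fit$folds[[1]], fx$x[held, ])
  one <- summarize_importance(list(ex))
  expect_true(all(one$sd_across_folds == 0))   # single fold: no spread
  expect_identical(sort(one$rank), seq_len(nrow(one)))
  # planted importance ordering is recovered with graded shifts
  set.seed(77)
  n <- 600
  x <- data.frame(strong = rnorm(n), mid = rnorm(n), weak = rnorm(n),
                  noise = rnorm(n))
  cls <- rep(c("coding", "lncRNA"), length.out = n)
  x$strong <- x$strong + ifelse(cls == "coding", 2.5, -2.5)
  x$mid <- x$mid + ifelse(cls == "coding", 1.0, -1.0)
  x$weak <- x$weak + ifelse(cls == "coding", 0.4, -0.4)
  rownames(x) <- sprintf("G%04d", 1:n)
  labels <- stats::setNames(cls, rownames(x))
  folds <- make_fold_splits(split(rownames(x), cls), k = 2, seed = 7)
  fit <- train_forests(x, labels, folds, forest_config(n_trees = 200, min_leaf = 10,
                                                       seed = 7))
  exps <- lapply(1:2, function(i) {
    held <- unlist(folds[[i]]$heldout_ids_by_class)
    explain_forest(fit$folds[[i]], x[held, ])
  })
  imp <- summarize_importance(exps)
  expect_identical(imp$feature[1:3], c("strong", "mid", "weak"))
})

test_that("fold hygiene: no explanation comes from a model trained on that transcript", {
  fx <- forest_fixture(n = 160, shift = 2)
  fit <- train_forests(fx$x, fx$labels, fx$folds, forest_config(n_trees = 40, seed = 6))
  for (i in seq_along(fit$folds)) {
    held <- unlist(fx$folds[[i]]$heldout_ids_by_class)
    expect_length(intersect(held, fit$folds[[i]]$train_ids), 0)
  }
})

test_that("threshold recalibration picks the Youden-J optimum on training OOB votes", {
  fx <- forest_fixture(n = 200, shift = 1)
  fit <- train_forests(fx$x, fx$labels, fx$folds,
                       forest_config(n_trees = 80, seed = 11, recalibrate = TRUE))
  thr <- fit$folds[[1]]$threshold
  expect_true(thr > 0 && thr < 1)
  oob <- fit$folds[[1]]$model$votes[, "coding"]
  yt <- fit$folds[[1]]$model$y
  j_at <- function(t) {
    pred <- ifelse(oob >= t, "coding", "lncRNA")
    mean(pred[yt == "coding"] == "coding") + mean(pred[yt == "lncRNA"] == "lncRNA") - 1
  }
  expect_gte(j_at(thr), j_at(0.5) - 1e-12)
})

test_that("the 2-D embedding is deterministic and separates planted clouds", {
  set.seed(15)
  x <- rbind(matrix(rnorm(120 * 4, 0), 120, 4),
             matrix(rnorm(120 * 4, 6), 120, 4))
  rownames(x) <- sprintf("E%03d", seq_len(nrow(x)))
  y1 <- embed_2d(x, perplexity = 20, n_iter = 250, seed = 8)
  expect_identical(dim(y1), c(240L, 2L))
  expect_identical(rownames(y1), rownames(x))
  y2 <- embed_2d(x, perplexity = 20, n_iter = 250, seed = 8)
  expect_identical(y1, y2)
  cls <- rep(1:2, each = 120)
  cent <- rbind(colMeans(y1[cls == 1, ]), colMeans(y1[cls == 2, ]))
  inter <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  intra <- mean(sqrt(rowSums((y1 - cent[cls, ])^2)))
  expect_gt(inter, intra)
  expect_error(embed_2d(x[1:50, ], perplexity = 20), "perplexity")
})
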