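test_that("preprocessing drops constants and one-hot encodes all levels", {
  d <- data.frame(
    a = c(1, 2, 3, 4), b = rep(5, 4),
    cat = c("x", "y", "z", "x"), flag = c("yes", "yes", "no", "no"),
    row.names = paste0("T", 1:4))
  ft <- feature_table(d, data.frame(
    name = c("a", "b", "cat", "flag"),
    kind = c("continuous", "continuous", "categorical", "categorical"),
    source = "ml_tool", units = ""))
  prep <- preprocess_features(ft)
  expect_identical(colnames(prep$continuous), "a")
  expect_setequal(colnames(prep$indicators),
                  c("cat=x", "cat=y", "cat=z", "flag=no", "flag=yes"))
  expect_identical(prep$dropped$name, "b")
  expect_identical(prep$dropped$reason, "constant")
  expect_equal(unname(unlist(prep$indicators["T1", c("cat=x", "cat=y")])), c(1, 0))
  # table with no categoricals -> empty indicator block
  ft2 <- feature_table(d[, 1:2])
  expect_equal(ncol(preprocess_features(ft2)$indicators), 0)
})

test_that("feature clustering recovers planted redundant blocks", {
  set.seed(5)
  n <- 300
  g1 <- rnorm(n); g2 <- rnorm(n)
  x <- data.frame(
    b1f1 = g1 + rnorm(n, 0, 0.1), b1f2 = g1 + rnorm(n, 0, 0.1),
    b1f3 = g1 + rnorm(n, 0, 0.1), b1f4 = g1 + rnorm(n, 0, 0.1),
    b1f5 = g1 + rnorm(n, 0, 0.1),
    b2f1 = g2 + rnorm(n, 0, 0.1), b2f2 = g2 + rnorm(n, 0, 0.1),
    b2f3 = g2 + rnorm(n, 0, 0.1), b2f4 = g2 + rnorm(n, 0, 0.1),
    b2f5 = g2 + rnorm(n, 0, 0.1),
    ind1 = rnorm(n), ind2 = rnorm(n), ind3 = rnorm(n))
  cl <- cluster_features(x)
  m <- cl$membership
  expect_length(unique(m[paste0("b1f", 1:5)]), 1)
  expect_length(unique(m[paste0("b2f", 1:5)]), 1)
  expect_false(m[["b1f1"]] == m[["b2f1"]])
  # an exactly duplicated feature has zero distance: always co-clustered
  x$dup <- x$b1f1
  m2 <- cluster_features(x)$membership
  expect_identical(m2[["dup"]], m2[["b1f1"]])
  # anti-correlated features are treated as redundant (d = 1 - |rho|)
  x$neg <- -x$b1f1 + rnorm(n, 0, 0.05)
  m3 <- cluster_features(x)$membership
  expect_identical(m3[["neg"]], m3[["b1f1"]])
  expect_warning(cluster_features(x[, 1:2]), "fewer than 3")
})

test_that("representative selection honors forced features, effects, and seeds", {
  membership <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L)
  clustering <- structure(list(membership = membership), class = "feature_clustering")
  eff <- c(a = 0.1, b = -0.4, c = 0.2, d = 0.2, e = 0)
  reps <- select_feature_representatives(clustering, "max_effect", effect = eff)
  expect_identical(reps, c("b", "c", "e"))  # |−0.4| wins; tie c/d -> lexicographic
  reps <- select_feature_representatives(clustering, "max_effect", effect = eff,
                                         forced = "a")
  expect_identical(reps[1], "a")            # forced wins its cluster
  expect_error(
    select_feature_representatives(clustering, "max_effect", effect = eff,
                                   forced = c("a", "b")),
    "two forced")
  r1 <- select_feature_representatives(clustering, "random", seed = 9)
  r2 <- select_feature_representatives(clustering, "random", seed = 9)
  expect_identical(r1, r2)
  expect_identical(r1[3], "e")              # singleton cluster: its only member
})

test_that("Vargha-Delaney A matches pair enumeration and its anchors", {
  # complete separation
  expect_equal(mannwhitney_vda(c(4, 5, 6), c(1, 2, 3))$cVDA, 0.5)
  expect_equal(mannwhitney_vda(c(1, 2, 3), c(4, 5, 6))$cVDA, -0.5)
  # identical samples
  expect_equal(mannwhitney_vda(c(1, 2, 3), c(1, 2, 3))$cVDA, 0)
  # hand enumeration: x={1,2}, y={1,3}: pairs (1,1)=.5 (1,3)=0 (2,1)=1 (2,3)=0
  r <- mannwhitney_vda(c(1, 2), c(1, 3))
  expect_equal(r$A, 0.375)
  expect_equal(r$cVDA, -0.125)
  # rank-sum identity vs direct pair counting on random instances (with ties)
  set.seed(21)
  for (i in 1:50) {
    nx <- sample(2:40, 1); ny <- sample(2:40, 1)
    x <- sample(1:8, nx, replace = TRUE)
    y <- sample(1:8, ny, replace = TRUE)
    a_pairs <- mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(mannwhitney_vda(x, y)$A, a_pairs)
  }
  expect_error(mannwhitney_vda(numeric(0), 1:3), "nonempty")
})

test_that("A(x,y) + A(y,x) = 1 over random sample pairs", {
  set.seed(31)
  for (i in 1:2000) {
    nx <- sample(2:25, 1); ny <- sample(2:25, 1)
    x <- round(rnorm(nx), sample(0:2, 1))
    y <- round(rnorm(ny), sample(0:2, 1))
    expect_equal(mannwhitney_vda(x, y)$A + mannwhitney_vda(y, x)$A, 1)
  }
})

test_that("Mann-Whitney p-values track the base-R implementation", {
  set.seed(41)
  # exact path (no ties, small)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  expect_equal(mannwhitney_vda(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value)
  expect_identical(mannwhitney_vda(x, y)$method, "exact")
  # normal approximation with tie correction (no continuity correction)
  x <- sample(1:6, 60, replace = TRUE); y <- sample(2:7, 80, replace = TRUE)
  expect_equal(mannwhitney_vda(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
})

test_that("chi-squared, Cramer's V and odds ratio match hand computations", {
  r <- chisq_cramers(rbind(c(30, 10), c(10, 30)))
  expect_equal(r$chi2, 20)   # all expected counts are 20
  expect_equal(r$V, 0.5)
  expect_equal(r$OR, 9)
  expect_equal(r$p, stats::chisq.test(rbind(c(30, 10), c(10, 30)),
                                      correct = FALSE)$p.value)
  # perfect association
  expect_equal(chisq_cramers(rbind(c(25, 0), c(0, 25)))$V, 1)
  # proportional rows -> independence
  expect_equal(chisq_cramers(rbind(c(10, 20), c(20, 40)))$V, 0)
  # Haldane correction engages on zero cells
  expect_equal(chisq_cramers(rbind(c(5, 0), c(2, 3)))$OR,
               (5.5 * 3.5) / (0.5 * 2.5))
  expect_error(chisq_cramers(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chisq_cramers(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("BH adjustment is the monotone step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment flags planted complete separation with the right direction", {
  n <- 60
  groups <- factor(rep(c("low", "high"), each = n),
                   levels = c("low", "intermediate", "high"))
  classes <- rep(c("coding", "lncRNA"), n)
  cont <- data.frame(sep = c(rnorm(n, 10), rnorm(n, -10)),
                     null = rnorm(2 * n))
  ind <- data.frame(flag = c(rbinom(n, 1, 0.9), rbinom(n, 1, 0.1)))
  res <- run_enrichment(cont, ind, classes, groups, comparisons = "low_vs_high")
  sep_row <- res[res$feature == "sep", ]
  expect_true(sep_row$significant)
  expect_equal(sep_row$effect, 0.5)     # complete separation
  expect_identical(sep_row$direction, "first")
  expect_true(res[res$feature == "flag", ]$odds_ratio > 1)
  # a comparison with an empty group is skipped and reported
  res2 <- run_enrichment(cont, ind, classes, groups,
                         comparisons = "lnc_vs_pc_high")
  expect_true(nrow(res2[res2$comparison == "lnc_vs_pc_high", ]) > 0)
  g3 <- factor(rep("low", 2 * n), levels = levels(groups))
  res3 <- run_enrichment(cont, ind, classes, g3, comparisons = "low_vs_high")
  expect_identical(attr(res3, "skipped"), "low_vs_high")
})
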