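#' 2-D t-SNE embedding for feature-space inspection
#'
#' Exact (dense) t-distributed stochastic neighbor embedding: Gaussian input
#' affinities with per-point bandwidths found by bisection to match the
#' target perplexity, symmetrized and normalized; Student-t output
#' affinities; gradient descent with momentum (0.5 for the first 250
#' iterations, 0.8 after), adaptive per-coordinate gains, and 4x early
#' exaggeration of the input affinities for the first 100 iterations.
#' Deterministic given the seed (the only randomness is the initial
#' configuration). Intended for visual inspection of transcript feature
#' space, not as a quantitative statistic.
#'
#' @param x numeric matrix/data.frame, one row per transcript; needs at
#'   least `3 * perplexity` rows.
#' @param perplexity effective number of neighbors (default 30).
#' @param n_iter gradient iterations (default 1000).
#' @param seed integer seed for the initial configuration.
#' @param eta learning rate (default 200).
#' @return numeric matrix `n x 2` (rownames preserved).
#' @export
embed_2d <- function(x, perplexity = 30, n_iter = 1000, seed = 1L, eta = 200) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3 * perplexity) {
    stop(sprintf("t-SNE needs at least 3 * perplexity = %d rows (got %d); lower the perplexity",
                 ceiling(3 * perplexity), n))
  }
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- with_seed(stage_seed(seed, "embedding"),
                 matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    pp <- if (iter <= 100) p * 4 else p
    momentum <- if (iter <= 250) 0.5 else 0.8
    sum_y <- rowSums(y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pp - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  rownames(y) <- rownames(x)
  colnames(y) <- c("tsne1", "tsne2")
  y
}

# per-point bandwidth bisection so each conditional distribution has the
# requested perplexity
tsne_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
        pi_row <- rep(0, length(di))
      } else {
        pi_row <- w / sw
        h <- -sum(pi_row[pi_row > 0] * log(pi_row[pi_row > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) {  # entropy too high: sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- pi_row
  }
  p
}
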