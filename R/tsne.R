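# Exact t-SNE (t-distributed stochastic neighbour embedding) on a
# precomputed distance matrix. Chemical-space sets here are small (tens
# to a few thousand molecules), so the exact O(n^2) formulation is used:
# per-point bandwidths found by binary search on the perplexity,
# symmetrized input affinities, Student-t low-dimensional kernel, and
# momentum gradient descent with early exaggeration.

tsne_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p[] <- 1e-12; s <- sum(p) }
      p <- p / s
      h <- -sum(p * log(pmax(p, 1e-12)))   # Shannon entropy
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# dist: an n x n symmetric distance matrix.
tsne_embed <- function(dist, perplexity, seed = 1L, n_iter = 500L,
                       learning_rate = 100) {
  n <- nrow(dist)
  stopifnot(n >= 5L)
  if (perplexity >= n)
    stop("perplexity (", perplexity, ") must be smaller than the number ",
         "of items (", n, ")")
  P <- tsne_affinities(dist^2, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L))
  gains <- matrix(1, n, 2L); inc <- matrix(0, n, 2L)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100L) 4 else 1       # early exaggeration
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    mult <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == 100L) momentum <- 0.8
  }
  Y
}
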