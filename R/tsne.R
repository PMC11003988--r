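# Exact (dense) t-SNE for small item counts. Quadratic in the number of
# items, which is ample for compound response profiles (hundreds of items);
# deterministic under a fixed seed.

# per-point precision calibration: binary search on beta = 1/(2 sigma^2)
# until the conditional distribution's perplexity matches the target
tsne_affinities <- function(d2, perplexity, tol = 1e-5) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pi_row <- w }
      else {
        pi_row <- w / sw
        h <- -sum(pi_row[pi_row > 0] * log(pi_row[pi_row > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) { beta_min <- beta; beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2 }
      else { beta_max <- beta; beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2 }
    }
    p[i, -i] <- pi_row
  }
  p
}

# x: items x dims; returns items x 2 coordinates
tsne_exact <- function(x, perplexity = 30, seed = 1, max_iter = 400,
                       eta = 100, momentum = c(0.5, 0.8), exaggeration = 12,
                       exaggeration_iters = 100) {
  n <- nrow(x)
  assert_that(perplexity < n, "perplexity must be < number of items")
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  pe <- p * exaggeration
  for (iter in seq_len(max_iter)) {
    pp <- if (iter <= exaggeration_iters) pe else p
    yd2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + yd2); diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    stiff <- 4 * (pp - q) * num
    grad <- (diag(rowSums(stiff)) - stiff) %*% y
    mom <- if (iter <= 250) momentum[1] else momentum[2]
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
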