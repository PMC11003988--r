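test_that("IC50 regression recovers exact fits and matches the R^2 identity", {
  # perfectly collinear points
  auc <- c(1, 2, 3, 4, 5)
  ic50 <- 2^(0.5 + 2 * auc)
  rep1 <- regress_ic50_vs_auc(ic50, auc)
  expect_equal(rep1$r_squared, 1, tolerance = 1e-12)
  expect_equal(rep1$slope, 2, tolerance = 1e-10)
  expect_equal(rep1$intercept, 0.5, tolerance = 1e-10)
  # constructed orthogonality: predictor uncorrelated with outcome
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -1, 0, -1, 1)          # even function: cor(x, y) = 0
  rep2 <- regress_ic50_vs_auc(2^y, x)
  expect_equal(rep2$r_squared, 0, tolerance = 1e-12)
  # random fixtures: R^2 equals squared Pearson correlation, and the loop oracle
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    auc <- stats::rnorm(n)
    lic <- 0.3 * auc + stats::rnorm(n)
    r <- regress_ic50_vs_auc(2^lic, auc)
    expect_equal(r$r_squared, stats::cor(lic, auc)^2, tolerance = 1e-10)
    fit <- stats::lm(lic ~ auc)
    ss_res <- 0; ss_tot <- 0; mbar <- mean(lic)
    for (i in seq_len(n)) {
      ss_res <- ss_res + (lic[i] - stats::fitted(fit)[[i]])^2
      ss_tot <- ss_tot + (lic[i] - mbar)^2
    }
    expect_equal(r$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-10)
  }
  expect_error(regress_ic50_vs_auc(c(1, -1, 2), 1:3), "positive")
  expect_error(regress_ic50_vs_auc(c(1, 2), c(1, 2)), "at least 3")
  const <- regress_ic50_vs_auc(c(2, 4, 8), c(1, 1, 1))
  expect_true(const$degenerate)
  expect_equal(const$r_squared, 0)
})

test_that("PCA embeddings respect rank structure and column reordering", {
  set.seed(3)
  u <- stats::rnorm(12); v <- stats::rnorm(6)
  rank1 <- outer(u, v)
  rownames(rank1) <- sprintf("item%02d", 1:12)
  emb <- response_embedding(rank1, "pca", standardize = FALSE)
  expect_lt(emb$explained_variance[2], 1e-20)
  # reordering profile dimensions leaves coordinates unchanged up to sign
  m <- matrix(stats::rnorm(60), 10, 6, dimnames = list(sprintf("i%02d", 1:10), NULL))
  e1 <- response_embedding(m, "pca", standardize = FALSE)
  e2 <- response_embedding(m[, c(4, 1, 6, 2, 3, 5)], "pca", standardize = FALSE)
  for (j in 1:2) {
    expect_equal(abs(e1$coords[, j]), abs(e2$coords[, j]), tolerance = 1e-9)
  }
})

test_that("t-SNE embeddings are deterministic under a fixed seed and validate inputs", {
  set.seed(14)
  m <- matrix(stats::rnorm(30 * 4), 30, 4,
              dimnames = list(sprintf("c%02d", 1:30), NULL))
  e1 <- response_embedding(m, "tsne", seed = 42, perplexity = 5)
  e2 <- response_embedding(m, "tsne", seed = 42, perplexity = 5)
  expect_identical(e1$coords, e2$coords)
  e3 <- response_embedding(m, "tsne", seed = 43, perplexity = 5)
  expect_false(identical(e1$coords, e3$coords))
  expect_error(response_embedding(m, "tsne", perplexity = 50), "perplexity")
  m[2, 2] <- NA
  expect_error(response_embedding(m, "tsne"), "missing")
})

test_that("embeddings separate planted response-profile clusters", {
  set.seed(6)
  centers <- rbind(rep(0, 8), rep(4, 8))
  grp <- rep(1:2, each = 10)
  m <- centers[grp, ] + matrix(stats::rnorm(20 * 8, sd = 0.5), 20, 8)
  rownames(m) <- sprintf("cmp%02d", 1:20)
  for (method in c("pca", "tsne")) {
    emb <- response_embedding(m, method, seed = 2, perplexity = 5)
    sil <- cluster::silhouette(grp, stats::dist(emb$coords))
    expect_gt(mean(sil[, "sil_width"]), 0)
  }
})

test_that("feature contrasts are zero for identical groups and rank planted shifts", {
  set.seed(21)
  base <- matrix(stats::runif(8 * 4), 8, 4,
                 dimnames = list(sprintf("f%d", 1:8), NULL))
  dup <- cbind(base, base)
  colnames(dup) <- sprintf("s%02d", 1:8)
  groups <- rep(c("A", "B"), each = 4)
  ct <- feature_contrast(dup, groups, top_k = 8)
  expect_true(all(abs(ct$contrast) < 1e-12))
  # planted +3-pooled-sd shift in group A only
  m <- matrix(stats::rnorm(6 * 10), 6, 10,
              dimnames = list(sprintf("f%d", 1:6), sprintf("s%02d", 1:10)))
  g <- rep(c("A", "B"), each = 5)
  m["f3", g == "A"] <- m["f3", g == "A"] + 3 * stats::sd(m["f3", ])
  ct <- feature_contrast(m, g, top_k = 6)
  topA <- ct[ct$group == "A" & ct$rank == 1, ]
  expect_identical(as.character(topA$feature), "f3")
  expect_gt(topA$contrast, 0)
  # two-group antisymmetry under label swap
  g2 <- rep(c("B", "A"), each = 5)
  ct2 <- feature_contrast(m, g2, top_k = 6)
  a1 <- ct[ct$group == "A", c("feature", "contrast")]
  b2 <- ct2[ct2$group == "A", c("feature", "contrast")]
  merged <- merge(a1, b2, by = "feature")
  expect_equal(merged$contrast.x, -merged$contrast.y, tolerance = 1e-12)
  # invariance to a common positive affine rescaling of one feature
  m2 <- m; m2["f3", ] <- 100 + 7 * m2["f3", ]
  ct3 <- feature_contrast(m2, g, top_k = 6)
  expect_equal(ct3[ct3$group == "A", "contrast"],
               ct[ct$group == "A", "contrast"], tolerance = 1e-9)
})
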