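# helper to fabricate a base_model_result with given OOF predictions and a
# constant-prediction serving model (1-NN on a single training point)
fake_result <- function(tag, oof, serve_value = mean(oof)) {
  structure(list(family = tag, params = list(), trial = 1L, oof = oof,
                 validation_score = NA_real_,
                 models = list(list(kind = "knn",
                                    x = matrix(0.5, 1, 2,
                                               dimnames = list(NULL, c("A", "B"))),
                                    y = serve_value, k = 1L,
                                    weighting = "uniform"))),
            class = "base_model_result")
}

test_that("a perfect base model takes all the weight", {
  y <- c(1, 2, 3, 4)
  good <- fake_result("gbm", y)
  bad <- fake_result("knn_uniform", y + 2)
  ens <- fit_weighted_ensemble(list(good, bad), y)
  expect_equal(unname(ens$weights["gbm"]), 1)
  expect_equal(ens$oof_mse, 0)
})

test_that("models with exactly opposite errors are mixed equally to zero error", {
  y <- c(2, 4, 6, 8, 10)
  e <- c(1, -1, 0.5, -0.5, 2)
  ens <- fit_weighted_ensemble(list(fake_result("gbm", y + e),
                                    fake_result("nnet", y - e)), y)
  expect_equal(unname(ens$weights), c(0.5, 0.5))
  expect_equal(ens$oof_mse, 0, tolerance = 1e-12)
})

test_that("ensemble OOF MSE never exceeds the best base model's (property)", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    y <- stats::rnorm(n)
    results <- lapply(seq_len(sample(2:6, 1)), function(i) {
      fake_result(paste0("m", i), y + stats::rnorm(n, sd = stats::runif(1, 0.1, 2)))
    })
    ens <- fit_weighted_ensemble(results, y)
    base_mse <- vapply(results, function(r) mean((r$oof - y)^2), 0)
    expect_lte(ens$oof_mse, min(base_mse) + 1e-12)
    expect_equal(sum(ens$weights), 1)
    expect_true(all(ens$weights >= 0))
    expect_lte(length(ens$trace), 100)
  }
})

test_that("greedy solution matches a simplex grid search on 3-model fixtures", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 40
    y <- stats::rnorm(n)
    oofs <- lapply(1:3, function(i) y + stats::rnorm(n, sd = stats::runif(1, 0.2, 1.5)))
    results <- Map(fake_result, paste0("m", 1:3), oofs)
    ens <- fit_weighted_ensemble(results, y, n_bags = 0)
    # dense grid over the weight simplex, step 0.05
    grid_best <- Inf
    for (w1 in seq(0, 1, 0.05)) for (w2 in seq(0, 1 - w1, 0.05)) {
      w3 <- 1 - w1 - w2
      mix <- w1 * oofs[[1]] + w2 * oofs[[2]] + w3 * oofs[[3]]
      grid_best <- min(grid_best, mean((mix - y)^2))
    }
    expect_lte(ens$oof_mse, grid_best + 1e-9)
  }
})

test_that("base-result order only affects roster-order tie breaking", {
  set.seed(23)
  y <- stats::rnorm(30)
  a <- fake_result("a", y + stats::rnorm(30, sd = 0.5))
  b <- fake_result("b", y + stats::rnorm(30, sd = 0.8))
  c_ <- fake_result("c", y + stats::rnorm(30, sd = 1.1))
  e1 <- fit_weighted_ensemble(list(a, b, c_), y)
  e2 <- fit_weighted_ensemble(list(c_, b, a), y)
  expect_equal(e1$weights[c("a", "b", "c")], e2$weights[c("a", "b", "c")],
               tolerance = 1e-12)
  expect_equal(e1$oof_mse, e2$oof_mse, tolerance = 1e-12)
})

test_that("ensemble predictions combine per-family serving predictions by weight", {
  y <- c(1, 2, 3, 4, 5)
  # two constant-serving families at 0 and 1 with engineered equal OOF errors
  f0 <- fake_result("gbm", y + c(1, -1, 1, -1, 1), serve_value = 0)
  f1 <- fake_result("nnet", y - c(1, -1, 1, -1, 1), serve_value = 1)
  ens <- fit_weighted_ensemble(list(f0, f1), y)
  expect_equal(unname(ens$weights), c(0.5, 0.5))
  scaler <- fit_scaler(matrix(c(0, 1, 0, 1), 2, 2,
                              dimnames = list(c("A", "B"), c("t1", "t2"))))
  bundle <- predictor_bundle("cmp", c("A", "B"), scaler, NULL,
                             list(f0, f1), ens, list())
  q <- matrix(0.5, 2, 3, dimnames = list(c("A", "B"), c("q1", "q2", "q3")))
  pred <- predict_bundle(bundle, q, per_family = TRUE)
  expect_equal(unname(pred$ensemble), rep(0.5, 3))
  expect_equal(unname(pred$per_family[, "gbm"]), rep(0, 3))
  # single-model bundle returns that family's prediction exactly
  ens1 <- fit_weighted_ensemble(list(f1), y)
  b1 <- predictor_bundle("cmp", c("A", "B"), scaler, NULL, list(f1), ens1, list())
  expect_equal(unname(predict_bundle(b1, q)), rep(1, 3))
  # missing query features are reported
  expect_error(predict_bundle(bundle, q[1, , drop = FALSE]), "B")
})

test_that("NaN in OOF vectors and empty input are rejected", {
  y <- 1:5 / 2
  bad <- fake_result("gbm", c(1, NaN, 3, 4, 5))
  expect_error(fit_weighted_ensemble(list(bad), y), "NaN")
  expect_error(fit_weighted_ensemble(list(), y), "at least one")
})
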