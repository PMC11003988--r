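# The nine base learner families and their random-search spaces.
#
# Families (roster order is also the deterministic tie-break order for the
# weighted ensemble): three boosted-tree variants (xgboost: a standard
# configuration, an extra-randomized column-subsampled variant, and a
# higher-capacity variant), two single-hidden-layer neural networks (nnet),
# random forest and extremely randomized trees (ranger), and uniform /
# distance-weighted k-nearest-neighbour regressors.
#
# Search spaces are deliberately desk-scale: ranges are standard for tabular
# regression at a few hundred samples and features, and every fit is
# single-threaded and seeded so results are reproducible on one platform.

runif_int <- function(lo, hi) sample(seq.int(lo, hi), 1)
logunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

fit_xgb <- function(x, y, params, seed) {
  p <- list(objective = "reg:squarederror", tree_method = "hist",
            max_bin = 32L, nthread = 1L, seed = seed,
            max_depth = params$max_depth, eta = params$eta,
            subsample = params$subsample,
            min_child_weight = params$min_child_weight)
  if (!is.null(params$colsample_bytree)) p$colsample_bytree <- params$colsample_bytree
  if (!is.null(params$colsample_bynode)) p$colsample_bynode <- params$colsample_bynode
  if (!is.null(params$lambda)) p$lambda <- params$lambda
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  m <- xgboost::xgb.train(params = p, data = d, nrounds = params$nrounds, verbose = 0)
  list(kind = "xgb", model = m)
}

fit_nnet <- function(x, y, params, seed) {
  # targets rescaled to [0,1] for stable optimization, mapped back at predict
  ymin <- min(y); yrng <- max(y) - ymin
  ys <- if (yrng == 0) rep(0.5, length(y)) else (y - ymin) / yrng
  m <- with_seed(seed,
    nnet::nnet(x, ys, size = params$size, decay = params$decay,
               maxit = params$maxit, linout = TRUE, trace = FALSE,
               MaxNWts = 100000))
  list(kind = "nnet", model = m, ymin = ymin, yrng = yrng)
}

fit_ranger <- function(x, y, params, seed) {
  mtry <- max(1L, min(ncol(x), floor(params$mtry_frac * ncol(x))))
  m <- ranger::ranger(x = x, y = y, num.trees = params$num_trees, mtry = mtry,
                      min.node.size = params$min_node_size,
                      splitrule = params$splitrule %||% "variance",
                      replace = params$replace %||% TRUE,
                      sample.fraction = params$sample_fraction %||% 1,
                      num.threads = 1, seed = seed)
  list(kind = "ranger", model = m)
}

fit_knn <- function(x, y, params, seed) {
  list(kind = "knn", x = x, y = y,
       k = min(params$k, nrow(x)), weighting = params$weighting)
}

predict_knn <- function(m, x) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(m$x)) +
    matrix(rowSums(m$x^2), nrow(x), nrow(m$x), byrow = TRUE) -
    2 * x %*% t(m$x)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(m$k)]
    if (m$weighting == "uniform") {
      mean(m$y[nn])
    } else {
      d <- sqrt(row[nn])
      if (any(d == 0)) return(mean(m$y[nn[d == 0]]))
      w <- 1 / d
      sum(w * m$y[nn]) / sum(w)
    }
  })
}

predict_learner <- function(m, x) {
  switch(m$kind,
    xgb = predict(m$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    nnet = {
      p <- as.numeric(nnet:::predict.nnet(m$model, x))
      if (m$yrng == 0) rep(m$ymin, length(p)) else m$ymin + p * m$yrng
    },
    ranger = predict(m$model, data = x, num.threads = 1)$predictions,
    knn = predict_knn(m, x),
    stop_pdr("unknown learner kind: ", m$kind))
}

#' The nine-family base learner roster
#'
#' Returns the ordered list of learner family specifications used by
#' [train_compound()]. Each entry has a \code{tag}, a \code{sample_params}
#' function (draws one random-search trial from the family's hyperparameter
#' space using the current RNG stream) and a \code{fit} function.
#'
#' @return named list of 9 learner specifications, in roster order.
#' @export
learner_roster <- function() {
  list(
    gbm = list(
      tag = "gbm",
      sample_params = function(n, p) list(
        max_depth = runif_int(2, 6), eta = logunif(0.03, 0.3),
        nrounds = runif_int(15, 80), subsample = stats::runif(1, 0.6, 1),
        colsample_bytree = stats::runif(1, 0.5, 1),
        min_child_weight = runif_int(1, 8), lambda = logunif(0.3, 10)),
      fit = fit_xgb),
    gbm_xt = list(
      tag = "gbm_xt",
      sample_params = function(n, p) list(
        max_depth = runif_int(2, 6), eta = logunif(0.05, 0.3),
        nrounds = runif_int(15, 80), subsample = stats::runif(1, 0.6, 1),
        colsample_bynode = stats::runif(1, 0.3, 0.8),
        min_child_weight = runif_int(1, 8)),
      fit = fit_xgb),
    gbm_large = list(
      tag = "gbm_large",
      sample_params = function(n, p) list(
        max_depth = runif_int(3, 7), eta = logunif(0.02, 0.12),
        nrounds = runif_int(60, 150), subsample = stats::runif(1, 0.6, 1),
        colsample_bytree = stats::runif(1, 0.5, 1),
        min_child_weight = runif_int(1, 6), lambda = logunif(0.3, 10)),
      fit = fit_xgb),
    nnet = list(
      tag = "nnet",
      sample_params = function(n, p) list(
        size = runif_int(1, 4), decay = logunif(1e-3, 1),
        maxit = runif_int(25, 60)),
      fit = fit_nnet),
    nnet_wide = list(
      tag = "nnet_wide",
      sample_params = function(n, p) list(
        size = runif_int(2, 5), decay = logunif(1e-2, 3),
        maxit = runif_int(25, 60)),
      fit = fit_nnet),
    random_forest = list(
      tag = "random_forest",
      sample_params = function(n, p) list(
        num_trees = runif_int(50, 150), mtry_frac = stats::runif(1, 0.05, 0.5),
        min_node_size = runif_int(1, 10),
        sample_fraction = stats::runif(1, 0.6, 1), replace = TRUE,
        splitrule = "variance"),
      fit = fit_ranger),
    extra_trees = list(
      tag = "extra_trees",
      sample_params = function(n, p) list(
        num_trees = runif_int(50, 120), mtry_frac = stats::runif(1, 0.05, 0.4),
        min_node_size = runif_int(2, 10), sample_fraction = 1, replace = FALSE,
        splitrule = "extratrees"),
      fit = fit_ranger),
    knn_uniform = list(
      tag = "knn_uniform",
      sample_params = function(n, p) list(
        k = runif_int(1, max(2, min(25, n - 1))), weighting = "uniform"),
      fit = fit_knn),
    knn_distance = list(
      tag = "knn_distance",
      sample_params = function(n, p) list(
        k = runif_int(1, max(2, min(25, n - 1))), weighting = "distance"),
      fit = fit_knn)
  )
}
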