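# Downstream assessment: measured-IC50 vs predicted-AUC regression,
# 2-D embeddings of response profiles, and group-wise feature contrasts.

#' Regress log-transformed IC50 on predicted AUC
#'
#' Ordinary least squares of log2(IC50) on the predicted AUC, the
#' evaluation used to compare model predictions against independently
#' measured dose-response potencies.
#'
#' @param ic50 measured IC50 values (> 0).
#' @param predicted_auc predicted AUC values, same length.
#' @param log_base base for the IC50 log transform, default 2.
#' @param condition free-form tag recorded in the report (e.g. "RF3" or an
#'   algorithm name).
#' @return an \code{evaluation_report}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n}, \code{condition},
#'   \code{degenerate} (TRUE when the predictor was constant and R^2 is
#'   reported as 0).
#' @export
regress_ic50_vs_auc <- function(ic50, predicted_auc, log_base = 2,
                                condition = "original") {
  assert_that(length(ic50) == length(predicted_auc), "length mismatch")
  assert_that(length(ic50) >= 3, "need at least 3 points")
  assert_that(all(is.finite(ic50)) && all(is.finite(predicted_auc)),
              "non-finite values")
  assert_that(all(ic50 > 0), "IC50 values must be positive")
  y <- log(ic50, base = log_base)
  if (stats::var(predicted_auc) == 0) {
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          n = length(y), condition = condition,
                          degenerate = TRUE),
                     class = "evaluation_report"))
  }
  fit <- stats::lm(y ~ predicted_auc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(y), condition = condition,
                 degenerate = FALSE),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> [%s] n=%d  log(IC50) = %.3g + %.3g * AUC,  R^2 = %.3f\n",
              x$condition, x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' 2-D embedding of response profiles
#'
#' Embeds items (compounds as profiles over samples, or patients as profiles
#' over compounds, depending on how the matrix is oriented) into two
#' dimensions by PCA or t-SNE. With \code{standardize = TRUE} (default)
#' each profile dimension (column) is centred and scaled to unit variance
#' before embedding.
#'
#' @param profiles items x dimensions numeric matrix with item rownames and
#'   no missing entries.
#' @param method \code{"pca"} or \code{"tsne"}.
#' @param seed seed (t-SNE initialization; recorded for both methods).
#' @param perplexity t-SNE perplexity; default 30 capped at (n-1)/3.
#' @param standardize standardize columns before embedding, default TRUE.
#' @return an \code{embedding_result}: \code{coords} (items x 2 with item
#'   rownames), \code{method}, \code{seed}, and for PCA
#'   \code{explained_variance} (fractions for all components).
#' @export
response_embedding <- function(profiles, method = c("pca", "tsne"), seed = 1,
                               perplexity = NULL, standardize = TRUE) {
  method <- match.arg(method)
  assert_that(is.matrix(profiles) && nrow(profiles) >= 3,
              "profiles must be a matrix with >= 3 items")
  assert_that(!anyNA(profiles),
              "missing entries in the profile matrix; impute before embedding")
  x <- profiles
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  }
  if (method == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    coords <- pc$x[, 1:2, drop = FALSE]
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
    colnames(coords) <- c("x", "y")
    structure(list(coords = coords, method = "pca", seed = seed,
                   explained_variance = ev),
              class = "embedding_result")
  } else {
    if (is.null(perplexity)) perplexity <- min(30, (nrow(x) - 1) / 3)
    assert_that(perplexity < nrow(x), "perplexity must be < number of items")
    coords <- tsne_exact(x, perplexity = perplexity, seed = seed)
    dimnames(coords) <- list(rownames(profiles), c("x", "y"))
    structure(list(coords = coords, method = "tsne", seed = seed,
                   perplexity = perplexity),
              class = "embedding_result")
  }
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %s, %d items\n", x$method, nrow(x$coords)))
  invisible(x)
}

#' Write an embedding as TSV (item, x, y)
#' @param embedding an \code{embedding_result}.
#' @param path output path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(item = rownames(embedding$coords),
                   x = embedding$coords[, 1], y = embedding$coords[, 2])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group-wise feature contrasts
#'
#' For each feature and group: the standardized one-vs-rest mean difference
#' (group mean minus rest mean, divided by the pooled standard deviation,
#' with a small variance floor for numerically constant features). This is a
#' descriptive ranking statistic, not a hypothesis test. Returns each
#' group's \code{top_k} features by signed contrast.
#'
#' @param features features x samples matrix (scores on a common scale).
#' @param groups named character/factor vector assigning samples to groups
#'   (names = sample IDs), or an unnamed vector aligned with the columns.
#' @param top_k number of top features per group, default 10.
#' @param var_floor variance floor, default 1e-8.
#' @return a data.frame (group, feature, contrast, group_mean, rest_mean,
#'   rank) containing the top_k features per group by descending contrast.
#' @export
feature_contrast <- function(features, groups, top_k = 10, var_floor = 1e-8) {
  v <- feature_values(features)
  if (!is.null(names(groups))) {
    assert_that(all(colnames(v) %in% names(groups)), "groups missing for some samples")
    groups <- groups[colnames(v)]
  } else {
    assert_that(length(groups) == ncol(v), "groups length must match sample count")
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  assert_that(length(lv) >= 2, "need at least 2 groups")
  assert_that(all(table(groups) >= 1), "a group has zero samples")
  out <- do.call(rbind, lapply(lv, function(g) {
    in_g <- groups == g
    m1 <- rowMeans(v[, in_g, drop = FALSE])
    m0 <- rowMeans(v[, !in_g, drop = FALSE])
    n1 <- sum(in_g); n0 <- sum(!in_g)
    v1 <- apply(v[, in_g, drop = FALSE], 1, stats::var)
    v0 <- apply(v[, !in_g, drop = FALSE], 1, stats::var)
    v1[is.na(v1)] <- 0; v0[is.na(v0)] <- 0
    pooled <- ((pmax(n1 - 1, 0)) * v1 + (pmax(n0 - 1, 0)) * v0) /
      pmax(n1 + n0 - 2, 1)
    d <- (m1 - m0) / sqrt(pmax(pooled, var_floor))
    o <- order(-d)[seq_len(min(top_k, nrow(v)))]
    data.frame(group = g, feature = rownames(v)[o], contrast = d[o],
               group_mean = m1[o], rest_mean = m0[o],
               rank = seq_along(o), row.names = NULL)
  }))
  out
}
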