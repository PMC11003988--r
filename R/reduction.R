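# Permutation feature importance against the deployed ensemble, top-percent
# feature retention (the RF20/RF10/RF3 conditions), and retraining.

# ensemble prediction on an already-scaled samples x features matrix
predict_scaled <- function(bundle, x) {
  w <- bundle$ensemble$weights
  active <- which(w > 0)
  preds <- numeric(nrow(x))
  for (j in active) {
    res <- bundle$base_results[[j]]
    fam <- rowMeans(matrix(vapply(res$models, function(m) predict_learner(m, x),
                                  numeric(nrow(x))), nrow = nrow(x)))
    preds <- preds + w[j] * fam
  }
  preds
}

#' Permutation feature importance for a trained bundle
#'
#' For each feature, the importance is the drop in the ensemble's score
#' (negative MSE, the training metric) when that feature's column is
#' permuted: \code{score(intact) - mean over shuffle sets of
#' score(permuted)}. Useful features have positive importance. The one-sided
#' p-value (null hypothesis: importance <= 0) comes from a t-test on the
#' per-shuffle-set score drops, the convention of tabular auto-ML importance
#' reports; an empirical count over 10 shuffle sets could never resolve
#' p below 1/11. Permutations are seeded per feature and shuffle set, derived from
#' \code{seed}. Scoring runs on a subsample of at most \code{subsample_size}
#' samples.
#'
#' @param bundle a trained \code{predictor_bundle}.
#' @param features raw enrichment features (an \code{enrichment_matrix} or
#'   features x samples matrix) covering the bundle's feature list.
#' @param labels named numeric AUC vector covering the feature samples.
#' @param n_shuffle_sets permutations per feature, default 10.
#' @param subsample_size scoring subsample cap, default 5000.
#' @param seed master seed for the permutations.
#' @param metadata metadata data.frame if the bundle uses metadata features.
#' @return an \code{importance_ranking}: data.frame (feature, importance,
#'   dispersion, p_value, rank) sorted by descending importance, with
#'   attributes \code{n_shuffle_sets} and \code{subsample_size}.
#' @export
permutation_importance <- function(bundle, features, labels,
                                   n_shuffle_sets = 10, subsample_size = 5000,
                                   seed = 1, metadata = NULL) {
  assert_that(inherits(bundle, "predictor_bundle"), "not a predictor_bundle")
  assert_that(n_shuffle_sets >= 1, "n_shuffle_sets must be >= 1")
  v <- feature_values(features)
  missing <- setdiff(bundle$feature_names, rownames(v))
  assert_that(length(missing) == 0,
              "features absent from input: ", paste(missing, collapse = ", "))
  v <- v[bundle$feature_names, , drop = FALSE]
  sids <- colnames(v)
  assert_that(all(sids %in% names(labels)), "labels missing for some samples")
  y <- as.numeric(labels[sids])
  scaled <- apply_scaler(bundle$scaler, v)
  if (!is.null(bundle$metadata_encoder)) {
    assert_that(!is.null(metadata), "bundle uses metadata features; supply metadata")
    scaled <- rbind(scaled, apply_metadata_encoder(bundle$metadata_encoder,
                                                   metadata, sids))
  }
  x <- t(scaled)
  n <- nrow(x)
  assert_that(n >= 2, "need at least 2 samples for permutation importance")
  if (n > subsample_size) {
    keep <- with_seed(derive_seed(seed, "subsample"), sample.int(n, subsample_size))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    n <- subsample_size
  }
  s0 <- -mean((predict_scaled(bundle, x) - y)^2)
  feats <- bundle$feature_names
  imp <- disp <- pval <- numeric(length(feats))
  for (j in seq_along(feats)) {
    # all shuffle sets stacked into one prediction call per model
    perms <- lapply(seq_len(n_shuffle_sets), function(s) {
      with_seed(derive_seed(seed, "perm", j, s), sample.int(n))
    })
    xs <- x[rep(seq_len(n), n_shuffle_sets), , drop = FALSE]
    col <- x[, feats[j]]
    xs[, feats[j]] <- unlist(lapply(perms, function(p) col[p]))
    pred <- predict_scaled(bundle, xs)
    s_perm <- vapply(seq_len(n_shuffle_sets), function(s) {
      idx <- (s - 1) * n + seq_len(n)
      -mean((pred[idx] - y)^2)
    }, 0)
    drops <- s0 - s_perm
    imp[j] <- mean(drops)
    disp[j] <- if (n_shuffle_sets > 1) stats::sd(drops) else 0
    pval[j] <- if (n_shuffle_sets > 1 && disp[j] > 0) {
      stats::pt(mean(drops) / (disp[j] / sqrt(n_shuffle_sets)),
                df = n_shuffle_sets - 1, lower.tail = FALSE)
    } else if (imp[j] > 0) 0 else 1
  }
  o <- order(-imp)
  out <- data.frame(feature = feats[o], importance = imp[o],
                    dispersion = disp[o], p_value = pval[o],
                    rank = seq_along(feats))
  attr(out, "n_shuffle_sets") <- n_shuffle_sets
  attr(out, "subsample_size") <- min(subsample_size, n)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Write an importance ranking as TSV
#' @param ranking an \code{importance_ranking}.
#' @param path output path.
#' @export
write_importance <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a top-fraction feature-reduction plan
#'
#' Retains the top \code{max(1, floor(fraction * F))} features of the
#' importance ordering. The presets 0.20, 0.10 and 0.03 correspond to the
#' RF20, RF10 and RF3 conditions.
#'
#' @param ranking an \code{importance_ranking}.
#' @param fraction fraction of features to keep, in (0, 1].
#' @return a \code{reduction_plan} with \code{fraction} and \code{retained}.
#' @export
reduce_features <- function(ranking, fraction) {
  assert_that(is.numeric(fraction) && fraction > 0 && fraction <= 1,
              "fraction must be in (0, 1]")
  f <- nrow(ranking)
  keep <- max(1L, as.integer(floor(fraction * f)))
  structure(list(fraction = fraction,
                 retained = as.character(ranking$feature[seq_len(keep)])),
            class = "reduction_plan")
}

#' @export
print.reduction_plan <- function(x, ...) {
  cat(sprintf("<reduction_plan> top %.0f%% -> %d feature(s)\n",
              100 * x$fraction, length(x$retained)))
  invisible(x)
}

#' Retrain a compound predictor on a reduced feature set
#'
#' Runs the full training procedure ([train_predictor()]: scaler fit,
#' nine-family search, ensemble) restricted to the plan's retained features,
#' with the same configuration as the initial training. Provenance records
#' the feature fraction.
#'
#' @param em an \code{enrichment_matrix} of raw ssGSEA scores.
#' @param labels a [drug_response_table()].
#' @param compound compound ID.
#' @param plan a \code{reduction_plan} from [reduce_features()].
#' @param config the [training_config()] used for the initial training.
#' @param metadata optional metadata (Glioma+/Metadata+ conditions).
#' @return a \code{predictor_bundle} trained on the retained features.
#' @export
retrain_reduced <- function(em, labels, compound, plan, config, metadata = NULL) {
  assert_that(inherits(plan, "reduction_plan"), "plan must be a reduction_plan")
  train_predictor(em, labels, compound, config, metadata = metadata,
                  feature_subset = plan$retained,
                  feature_fraction = plan$fraction)
}
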