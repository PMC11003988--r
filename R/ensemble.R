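# Stack-two weighted ensemble: a convex combination of the base models,
# fitted by greedy forward selection with replacement on their out-of-fold
# predictions.

#' Fit the weighted ensemble over base-model OOF predictions
#'
#' Greedy ensemble selection with replacement: starting from the empty
#' ensemble, repeatedly add (with replacement) the base model whose inclusion
#' minimizes the OOF mean squared error of the running average, up to
#' \code{budget} picks; the best ensemble seen along the trace is returned.
#' Because the first pick is the single best base model and the best-so-far
#' ensemble is tracked, the returned ensemble's OOF MSE never exceeds the
#' best single model's. Ties between candidate picks are broken by roster
#' order.
#'
#' @param base_results list of \code{base_model_result} (from
#'   [train_compound()]) with complete OOF vectors on common samples.
#' @param labels numeric label vector the OOF predictions are aligned to.
#' @param budget maximum number of greedy picks, default 100.
#' @param n_bags number of bootstrap rows-subsample repetitions of the
#'   greedy selection whose weight vectors are averaged (the standard
#'   overfitting control for ensemble selection); 0 disables bagging and
#'   uses the plain greedy solution. Default 50.
#' @param bag_fraction fraction of OOF rows drawn (without replacement) per
#'   bag, default 0.5.
#' @param seed seed for the bag subsamples.
#' @return an \code{ensemble_model}: normalized nonnegative \code{weights}
#'   (named by family, summing to 1), the ordered selection \code{trace} of
#'   the full-data greedy pass, the ensemble \code{oof} vector and its
#'   \code{oof_mse}.
#' @export
fit_weighted_ensemble <- function(base_results, labels, budget = 100,
                                  n_bags = 50, bag_fraction = 0.5, seed = 1) {
  assert_that(length(base_results) >= 1, "need at least one base model")
  tags <- vapply(base_results, `[[`, "", "family")
  oof <- vapply(base_results, `[[`, numeric(length(labels)), "oof")
  oof <- matrix(oof, nrow = length(labels), dimnames = list(NULL, tags))
  assert_that(all(is.finite(oof)), "NaN/Inf in OOF predictions")
  assert_that(all(is.finite(labels)), "NaN/Inf in labels")
  n <- length(labels)
  greedy <- greedy_selection(oof, labels, budget)
  w <- greedy$weights
  if (n_bags > 0 && length(base_results) > 1) {
    bag_w <- vapply(seq_len(n_bags), function(b) {
      rows <- with_seed(derive_seed(seed, "ensemble_bag", b),
                        sample.int(n, max(2, floor(bag_fraction * n))))
      greedy_selection(oof[rows, , drop = FALSE], labels[rows], budget)$weights
    }, numeric(ncol(oof)))
    w_bagged <- rowMeans(bag_w)
    # keep the never-worse guarantee: fall back to the plain greedy solution
    # if the bagged weights do not also beat every single base model on OOF
    mse_bagged <- mean((as.numeric(oof %*% w_bagged) - labels)^2)
    if (mse_bagged <= min(colMeans((oof - labels)^2))) w <- w_bagged
  }
  ens_oof <- as.numeric(oof %*% w)
  structure(list(weights = stats::setNames(w, tags),
                 trace = tags[greedy$trace],
                 oof = ens_oof, oof_mse = mean((ens_oof - labels)^2)),
            class = "ensemble_model")
}

# plain greedy forward selection with replacement; returns the best-so-far
# normalized weight vector (its OOF MSE never exceeds the best single
# model's, because the first pick is the best single model)
greedy_selection <- function(oof, labels, budget) {
  n <- nrow(oof)
  counts <- integer(ncol(oof))
  run_sum <- numeric(n)
  best <- NULL
  trace <- integer(0)
  for (pick in seq_len(budget)) {
    # candidate MSE for adding each model to the running average
    cand_mse <- colMeans(((run_sum + oof) / pick - labels)^2)
    j <- which.min(cand_mse)  # first index wins ties = roster order
    counts[j] <- counts[j] + 1L
    run_sum <- run_sum + oof[, j]
    trace <- c(trace, j)
    if (is.null(best) || cand_mse[j] < best$mse) {
      best <- list(mse = cand_mse[j], counts = counts, picks = pick)
    }
  }
  list(weights = best$counts / best$picks, trace = trace[seq_len(best$picks)],
       mse = best$mse)
}

#' @export
print.ensemble_model <- function(x, ...) {
  w <- x$weights[x$weights > 0]
  cat("<ensemble_model> weights:",
      paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
      sprintf("(OOF MSE %.4g)\n", x$oof_mse))
  invisible(x)
}

#' Construct a predictor bundle
#'
#' The serializable per-compound artifact: fitted base models, ensemble
#' weights, the feature list and scaler state, and training provenance.
#'
#' @param compound_id compound identifier.
#' @param feature_names features the bundle consumes, in order.
#' @param scaler fitted \code{minmax_scaler}.
#' @param metadata_encoder fitted \code{metadata_encoder} or NULL.
#' @param base_results list of \code{base_model_result}.
#' @param ensemble fitted \code{ensemble_model}.
#' @param provenance list (config, seed, condition, feature fraction,
#'   validation scores, ...).
#' @return an object of class \code{predictor_bundle}.
#' @export
predictor_bundle <- function(compound_id, feature_names, scaler,
                             metadata_encoder = NULL, base_results, ensemble,
                             provenance) {
  structure(list(compound_id = compound_id, feature_names = feature_names,
                 scaler = scaler, metadata_encoder = metadata_encoder,
                 base_results = base_results, ensemble = ensemble,
                 provenance = provenance),
            class = "predictor_bundle")
}

#' @export
print.predictor_bundle <- function(x, ...) {
  cat(sprintf("<predictor_bundle> compound '%s': %d features, %d base families, ensemble OOF MSE %.4g\n",
              x$compound_id, length(x$feature_names),
              length(x$base_results), x$ensemble$oof_mse))
  invisible(x)
}

# per-family predictions: mean over the stored fold models
predict_families <- function(bundle, x) {
  vapply(bundle$base_results, function(res) {
    preds <- vapply(res$models, function(m) predict_learner(m, x),
                    numeric(nrow(x)))
    rowMeans(matrix(preds, nrow = nrow(x)))
  }, numeric(nrow(x))) |>
    matrix(nrow = nrow(x),
           dimnames = list(rownames(x),
                           vapply(bundle$base_results, `[[`, "", "family")))
}

#' Predict AUC for query samples with a trained bundle
#'
#' Query enrichment scores are scaled with the bundle's training scaler
#' (clipping to the training [0,1] range), each base family predicts as the
#' mean over its fold models, and the ensemble prediction is the
#' weight-combined result.
#'
#' @param bundle a \code{predictor_bundle}.
#' @param features query features: an \code{enrichment_matrix} or features x
#'   samples matrix of raw (unscaled) ssGSEA scores covering the bundle's
#'   feature list.
#' @param metadata metadata data.frame, required if the bundle was trained
#'   under \code{metadata_plus}.
#' @param per_family if TRUE, also return the per-family prediction matrix.
#' @return named numeric vector of predicted AUC per query sample; with
#'   \code{per_family = TRUE}, a list with \code{ensemble} and
#'   \code{per_family}.
#' @export
predict_bundle <- function(bundle, features, metadata = NULL, per_family = FALSE) {
  assert_that(inherits(bundle, "predictor_bundle"), "not a predictor_bundle")
  v <- feature_values(features)
  missing <- setdiff(bundle$feature_names, rownames(v))
  assert_that(length(missing) == 0,
              "query features missing: ", paste(missing, collapse = ", "))
  v <- v[bundle$feature_names, , drop = FALSE]
  scaled <- apply_scaler(bundle$scaler, v)
  if (!is.null(bundle$metadata_encoder)) {
    assert_that(!is.null(metadata),
                "bundle was trained with metadata features; supply metadata")
    scaled <- rbind(scaled, apply_metadata_encoder(bundle$metadata_encoder,
                                                   metadata, colnames(scaled)))
  }
  x <- t(scaled)
  fam <- predict_families(bundle, x)
  out <- stats::setNames(as.numeric(fam %*% bundle$ensemble$weights), rownames(x))
  if (per_family) list(ensemble = out, per_family = fam) else out
}

#' Save a predictor bundle to a directory
#'
#' Writes a human-readable \code{manifest.json} (provenance, feature list,
#' ensemble weights, validation scores) alongside \code{models.rds} holding
#' the fitted model objects.
#'
#' @param bundle a \code{predictor_bundle}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    compound_id = bundle$compound_id,
    feature_names = bundle$feature_names,
    ensemble_weights = as.list(bundle$ensemble$weights),
    ensemble_oof_mse = bundle$ensemble$oof_mse,
    provenance = bundle$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(bundle, file.path(dir, "models.rds"))
  invisible(dir)
}

#' Load a predictor bundle saved by [save_bundle()]
#' @param dir bundle directory.
#' @return a \code{predictor_bundle}.
#' @export
load_bundle <- function(dir) {
  path <- file.path(dir, "models.rds")
  assert_that(file.exists(path), "no bundle at ", dir)
  readRDS(path)
}
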