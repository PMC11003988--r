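# Per-compound supervised training: random hyperparameter search over the
# nine-family roster, scored by repeated k-fold out-of-fold (OOF) mean
# squared error. OOF predictions feed the stack-two weighted ensemble and
# the validation score.

#' Training configuration
#'
#' Desk-scale defaults (\code{n_trials = 16}, \code{repeats = 1}) keep a full
#' nine-family run tractable on one CPU; the full-scale settings used for
#' production-sized cohorts (\code{n_trials = 512}, \code{repeats = 3}) are
#' plain overrides.
#'
#' @param folds number of cross-validation folds k (>= 2), default 5.
#' @param repeats number of repeated k-fold rounds r (>= 1), default 1.
#' @param n_trials random-search trials per learner family, default 16.
#' @param seed master seed; all fold assignments, hyperparameter draws and
#'   model fits derive their seeds from it.
#' @param condition workflow variant: \code{"base"}, \code{"glioma_plus"}
#'   (training restricted to one disease label) or \code{"metadata_plus"}
#'   (clinical metadata appended to the features).
#' @param cohort_label disease label retained under \code{"glioma_plus"}.
#' @param metadata_columns metadata columns encoded under
#'   \code{"metadata_plus"}.
#' @param families optional character vector restricting the roster (used
#'   mainly in tests); default all nine.
#' @return an object of class \code{training_config}.
#' @export
training_config <- function(folds = 5, repeats = 1, n_trials = 16, seed = 1,
                            condition = c("base", "glioma_plus", "metadata_plus"),
                            cohort_label = "glioma",
                            metadata_columns = c("age", "sex"),
                            families = NULL) {
  condition <- match.arg(condition)
  assert_that(folds >= 2, "folds must be >= 2")
  assert_that(repeats >= 1, "repeats must be >= 1")
  assert_that(n_trials >= 1, "n_trials must be >= 1")
  roster <- names(learner_roster())
  if (is.null(families)) families <- roster
  assert_that(all(families %in% roster),
              "unknown learner family: ", paste(setdiff(families, roster), collapse = ", "))
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 condition = condition, cohort_label = cohort_label,
                 metadata_columns = metadata_columns, families = families),
            class = "training_config")
}

#' Validation score of out-of-fold predictions
#'
#' The negative mean squared error of OOF predictions against the labels;
#' values closer to zero are better.
#'
#' @param oof numeric OOF prediction vector.
#' @param labels numeric label vector of the same length.
#' @return a single number <= 0.
#' @export
validation_score <- function(oof, labels) {
  assert_that(length(oof) == length(labels), "length mismatch")
  assert_that(length(oof) >= 1, "empty vectors")
  -mean((oof - labels)^2)
}

#' Restrict a cohort to one disease label
#'
#' The "Glioma+" workflow variant: keeps only samples whose
#' \code{disease_label} matches.
#'
#' @param metadata data.frame with \code{sample_id} and \code{disease_label}.
#' @param disease_label label to retain.
#' @return the filtered metadata (same columns).
#' @export
cohort_filter <- function(metadata, disease_label) {
  assert_that("disease_label" %in% colnames(metadata),
              "metadata lacks a disease_label column")
  assert_that(disease_label %in% metadata$disease_label,
              "disease label '", disease_label, "' absent from the cohort")
  out <- metadata[metadata$disease_label == disease_label, , drop = FALSE]
  message(sprintf("cohort_filter: retained %d/%d samples with disease_label '%s'",
                  nrow(out), nrow(metadata), disease_label))
  out
}

# one fold-assignment vector (values 1..k) per repeat, shared by all learner
# families so that OOF predictions are comparable for stacking
make_fold_assignments <- function(n, k, r, seed, compound_id) {
  lapply(seq_len(r), function(rep) {
    with_seed(derive_seed(seed, compound_id, "folds", rep),
              sample(rep(seq_len(k), length.out = n)))
  })
}

# repeated k-fold OOF evaluation of one hyperparameter draw; OOF prediction
# per sample is the mean of its held-out predictions over repeats
oof_evaluate <- function(x, y, folds, fit, params, seed_base, keep_models = FALSE) {
  n <- length(y)
  acc <- numeric(n)
  models <- if (keep_models) list() else NULL
  for (rep in seq_along(folds)) {
    fa <- folds[[rep]]
    for (f in seq_len(max(fa))) {
      hold <- fa == f
      m <- fit(x[!hold, , drop = FALSE], y[!hold],
               params, derive_seed(seed_base, rep, f))
      acc[hold] <- acc[hold] + predict_learner(m, x[hold, , drop = FALSE])
      if (keep_models) models[[length(models) + 1]] <- m
    }
  }
  oof <- acc / length(folds)
  list(oof = oof, mse = mean((oof - y)^2), models = models)
}

#' Train all base learner families for one compound
#'
#' For each family, draws \code{n_trials} random hyperparameter settings,
#' scores each by r-repeat k-fold OOF mean squared error (fold assignments
#' are shared across families so OOF predictions are stackable), keeps the
#' best trial, and refits its fold models for serving. Fully reproducible
#' given the config seed on a fixed platform.
#'
#' @param x samples x features numeric matrix, scaled to [0,1].
#' @param y numeric label vector (AUC), aligned with rows of \code{x}.
#' @param config a [training_config()].
#' @param compound_id compound identifier (seeds are derived per compound).
#' @return list of \code{base_model_result} objects (one per family, roster
#'   order), each with \code{family}, \code{params}, \code{oof},
#'   \code{validation_score}, \code{models} (fold models of the best trial).
#' @export
train_compound <- function(x, y, config, compound_id = "compound") {
  assert_that(inherits(config, "training_config"), "config must be a training_config")
  n <- nrow(x)
  assert_that(n == length(y), "x and y disagree on sample count")
  assert_that(n >= 2 * config$folds,
              "need at least 2*k = ", 2 * config$folds,
              " samples; got ", n, " (use a smaller k)")
  rng <- range(x)
  assert_that(rng[1] >= -1e-8 && rng[2] <= 1 + 1e-8,
              "features must be scaled to [0,1]; run apply_scaler() first")
  if (stats::var(y) == 0) {
    warning("constant label vector; models will fit the constant", call. = FALSE)
  }
  folds <- make_fold_assignments(n, config$folds, config$repeats,
                                 config$seed, compound_id)
  roster <- learner_roster()[config$families]
  lapply(roster, function(fam) {
    draws <- with_seed(derive_seed(config$seed, compound_id, fam$tag, "search"),
                       lapply(seq_len(config$n_trials),
                              function(i) fam$sample_params(n, ncol(x))))
    best <- NULL
    for (t in seq_along(draws)) {
      res <- oof_evaluate(x, y, folds, fam$fit, draws[[t]],
                          derive_seed(config$seed, compound_id, fam$tag, t))
      if (is.null(best) || res$mse < best$mse) {
        best <- res; best$trial <- t
      }
    }
    final <- oof_evaluate(x, y, folds, fam$fit, draws[[best$trial]],
                          derive_seed(config$seed, compound_id, fam$tag, best$trial),
                          keep_models = TRUE)
    structure(list(family = fam$tag, params = draws[[best$trial]],
                   trial = best$trial, oof = final$oof,
                   validation_score = validation_score(final$oof, y),
                   models = final$models),
              class = "base_model_result")
  })
}

#' Train a complete per-compound predictor bundle
#'
#' End-to-end training for one compound: align expression-derived features
#' with the compound's AUC labels, optionally restrict the cohort
#' (Glioma+) or append clinical metadata (Metadata+), fit the [0,1] scaler
#' on the training samples, run the nine-family search, and fit the
#' stack-two weighted ensemble on the out-of-fold predictions.
#'
#' @param em an \code{enrichment_matrix} (raw ssGSEA scores, sets x samples).
#' @param labels a [drug_response_table()].
#' @param compound compound ID to train.
#' @param config a [training_config()].
#' @param metadata optional sample metadata data.frame (required for the
#'   \code{glioma_plus} and \code{metadata_plus} conditions).
#' @param feature_subset optional character vector of feature names to
#'   restrict training to (used by [retrain_reduced()]).
#' @param feature_fraction recorded in provenance (1 for a full run).
#' @return a \code{predictor_bundle}.
#' @export
train_predictor <- function(em, labels, compound, config, metadata = NULL,
                            feature_subset = NULL, feature_fraction = 1) {
  scores <- feature_values(em)
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, rownames(scores))
    assert_that(length(missing) == 0,
                "feature subset not present: ", paste(missing, collapse = ", "))
    # keep the matrix's canonical row order so that a full-fraction plan
    # reproduces the un-reduced run exactly
    scores <- scores[rownames(scores)[rownames(scores) %in% feature_subset], ,
                     drop = FALSE]
  }
  pairs <- align_training_pairs(scores, labels, compound)
  if (config$condition == "glioma_plus") {
    assert_that(!is.null(metadata), "glioma_plus requires sample metadata")
    meta_kept <- cohort_filter(metadata, config$cohort_label)
    pairs$sample_ids <- pairs$sample_ids[pairs$sample_ids %in% meta_kept$sample_id]
    assert_that(length(pairs$sample_ids) > 0,
                "no labelled samples left after the cohort filter")
    pairs$auc <- pairs$auc[pairs$sample_ids]
  }
  train_scores <- scores[, pairs$sample_ids, drop = FALSE]
  scaler <- fit_scaler(train_scores)
  scaled <- apply_scaler(scaler, train_scores)
  encoder <- NULL
  if (config$condition == "metadata_plus") {
    assert_that(!is.null(metadata), "metadata_plus requires sample metadata")
    scaled <- augment_with_metadata(scaled, metadata, config$metadata_columns)
    encoder <- attr(scaled, "encoder")
  }
  x <- t(scaled)
  y <- as.numeric(pairs$auc)
  base_results <- train_compound(x, y, config, compound)
  ens <- fit_weighted_ensemble(base_results, y)
  predictor_bundle(compound_id = compound, feature_names = rownames(scores),
                   scaler = scaler, metadata_encoder = encoder,
                   base_results = base_results, ensemble = ens,
                   provenance = list(
                     config = unclass(config), seed = config$seed,
                     condition = config$condition,
                     feature_fraction = feature_fraction,
                     n_train_samples = length(y),
                     validation_scores = c(
                       stats::setNames(vapply(base_results, `[[`, 0, "validation_score"),
                                       vapply(base_results, `[[`, "", "family")),
                       ensemble = validation_score(ens$oof, y))))
}
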