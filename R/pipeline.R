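# End-to-end workflow orchestration: read inputs, build features, train a
# bundle per compound (with optional importance/reduction/retraining),
# run downstream evaluation, and emit a manifest with provenance.

#' Build a workflow run configuration
#'
#' @param expression_path expression matrix (GCT or TSV, log2(TPM+1)).
#' @param gmt_path gene-set collection (GMT).
#' @param labels_path drug-response labels CSV (sample_id,compound_id,auc).
#' @param out_dir run output directory.
#' @param metadata_path optional metadata CSV.
#' @param expression_format \code{"gct"} or \code{"tsv"}.
#' @param alpha ssGSEA rank-weight exponent, default 0.75.
#' @param bounds gene-set size bounds after intersection, default c(5, 2000).
#' @param training a [training_config()]; its seed is overridden per
#'   compound by a seed derived from \code{seed} and the compound ID.
#' @param reduction_fractions numeric vector of top-fractions to retrain at
#'   (e.g. c(0.20, 0.10, 0.03)); empty for no reduction. The smallest
#'   fraction's bundle is the one used downstream.
#' @param importance_shuffle_sets shuffle sets for permutation importance,
#'   default 10.
#' @param importance_subsample subsample cap for importance scoring,
#'   default 5000.
#' @param embedding_method \code{"pca"} or \code{"tsne"} for the
#'   compound-response-profile embedding.
#' @param contrast_column metadata column used for group-wise feature
#'   contrasts (NULL to skip), default "disease_label".
#' @param seed master seed for the whole run.
#' @param resume skip compounds whose bundle directory already exists.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(expression_path, gmt_path, labels_path, out_dir,
                       metadata_path = NULL, expression_format = c("gct", "tsv"),
                       alpha = 0.75, bounds = c(5, 2000),
                       training = training_config(),
                       reduction_fractions = numeric(0),
                       importance_shuffle_sets = 10,
                       importance_subsample = 5000,
                       embedding_method = c("pca", "tsne"),
                       contrast_column = "disease_label",
                       seed = 1, resume = FALSE) {
  structure(list(expression_path = expression_path, gmt_path = gmt_path,
                 labels_path = labels_path, metadata_path = metadata_path,
                 expression_format = match.arg(expression_format),
                 out_dir = out_dir, alpha = alpha, bounds = bounds,
                 training = training,
                 reduction_fractions = sort(reduction_fractions, decreasing = TRUE),
                 importance_shuffle_sets = importance_shuffle_sets,
                 importance_subsample = importance_subsample,
                 embedding_method = match.arg(embedding_method),
                 contrast_column = contrast_column,
                 seed = as.integer(seed), resume = isTRUE(resume)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a \code{training}
#' mapping mirrors [training_config()].
#'
#' @param path YAML config path.
#' @param ... overrides applied on top of the file values.
#' @return a \code{run_config}.
#' @export
load_run_config <- function(path, ...) {
  assert_that(file.exists(path), "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$training) && !inherits(cfg$training, "training_config")) {
    cfg$training <- do.call(training_config, cfg$training)
  }
  do.call(run_config, cfg)
}

# stable hash of the scientific configuration for the manifest; the output
# location and resume flag do not change results and are excluded
config_hash <- function(config) {
  clean <- unclass(config)
  clean$out_dir <- NULL
  clean$resume <- NULL
  clean$training <- unclass(clean$training)
  json <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

rel_checksums <- function(out_dir, paths) {
  paths <- sort(paths)
  lapply(stats::setNames(paths, vapply(paths, function(p) {
    sub("^/", "", sub(normalizePath(out_dir, winslash = "/"), "",
                      normalizePath(p, winslash = "/"), fixed = TRUE))
  }, "")), function(p) unname(tools::md5sum(p)))
}

#' Run the full workflow
#'
#' Executes read -> ssGSEA -> scaling -> per-compound training and
#' ensembling -> optional permutation importance, feature reduction and
#' retraining -> downstream evaluation (response-profile embedding,
#' group-wise feature contrasts), writing bundles, rankings, reports and a
#' \code{manifest.json} capturing the seed, a config hash, per-compound
#' validation scores and a checksum for every emitted file. A stage error
#' aborts only the affected compound (recorded as failed in the manifest);
#' input errors abort the run.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; written to
#'   \code{out_dir/manifest.json}.
#' @export
run_workflow <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  for (p in c(config$expression_path, config$gmt_path, config$labels_path,
              config$metadata_path)) {
    assert_that(is.null(p) || file.exists(p), "input path not found: ", p %||% "")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- read_expression(config$expression_path, config$expression_format)
  sets <- read_gmt(config$gmt_path)
  labels <- read_drug_response(config$labels_path)
  metadata <- if (!is.null(config$metadata_path)) {
    read_sample_metadata(config$metadata_path)
  } else NULL
  em <- ssgsea_matrix(expr, sets, alpha = config$alpha, bounds = config$bounds)
  feat_path <- file.path(config$out_dir, "enrichment.tsv")
  utils::write.table(
    data.frame(feature = rownames(em$scores),
               apply(em$scores, 2, num_chr), check.names = FALSE),
    feat_path, sep = "\t", row.names = FALSE, quote = FALSE)
  emitted <- feat_path
  compound_entries <- list()
  final_bundles <- list()
  for (cid in compounds(labels)) {
    cdir <- file.path(config$out_dir, "bundles", cid)
    entry <- tryCatch({
      if (config$resume && file.exists(file.path(cdir, "original", "models.rds"))) {
        bundle <- load_bundle(file.path(cdir, "original"))
      } else {
        cfg_c <- config$training
        cfg_c$seed <- derive_seed(config$seed, cid)
        bundle <- train_predictor(em, labels, cid, cfg_c, metadata = metadata)
        save_bundle(bundle, file.path(cdir, "original"))
      }
      files <- file.path(cdir, "original", c("manifest.json", "models.rds"))
      scores <- list(original = bundle$provenance$validation_scores[["ensemble"]])
      final <- bundle
      if (length(config$reduction_fractions) > 0) {
        pairs <- align_training_pairs(em, labels, cid)
        ranking <- permutation_importance(
          bundle, em$scores[, pairs$sample_ids, drop = FALSE], pairs$auc,
          n_shuffle_sets = config$importance_shuffle_sets,
          subsample_size = config$importance_subsample,
          seed = derive_seed(config$seed, cid, "importance"),
          metadata = metadata)
        rank_path <- file.path(cdir, "importance.tsv")
        write_importance(ranking, rank_path)
        files <- c(files, rank_path)
        for (frac in config$reduction_fractions) {
          tag <- sprintf("rf%02.0f", 100 * frac)
          plan <- reduce_features(ranking, frac)
          cfg_c <- config$training
          cfg_c$seed <- derive_seed(config$seed, cid)
          red <- retrain_reduced(em, labels, cid, plan, cfg_c, metadata = metadata)
          save_bundle(red, file.path(cdir, tag))
          files <- c(files, file.path(cdir, tag, c("manifest.json", "models.rds")))
          scores[[tag]] <- red$provenance$validation_scores[["ensemble"]]
          final <- red
        }
      }
      emitted <- c(emitted, files)
      final_bundles[[cid]] <- final
      list(status = "succeeded", validation_scores = scores)
    }, error = function(e) {
      list(status = "failed", error = conditionMessage(e))
    })
    compound_entries[[cid]] <- entry
  }
  ok <- names(final_bundles)
  if (length(ok) >= 1) {
    pred <- vapply(final_bundles[ok], function(b) predict_bundle(b, em),
                   numeric(ncol(em$scores)))
    pred_mat <- t(matrix(pred, ncol = length(ok),
                         dimnames = list(colnames(em$scores), ok)))
    pred_path <- file.path(config$out_dir, "predicted_auc.tsv")
    utils::write.table(
      data.frame(compound_id = rownames(pred_mat),
                 apply(pred_mat, 2, num_chr), check.names = FALSE),
      pred_path, sep = "\t", row.names = FALSE, quote = FALSE)
    emitted <- c(emitted, pred_path)
    if (length(ok) >= 3) {
      method <- config$embedding_method
      emb <- response_embedding(pred_mat, method = method,
                                seed = derive_seed(config$seed, "embedding"))
      emb_path <- file.path(config$out_dir, paste0("embedding_", method, ".tsv"))
      write_embedding(emb, emb_path)
      emitted <- c(emitted, emb_path)
    }
  }
  if (!is.null(metadata) && !is.null(config$contrast_column) &&
      config$contrast_column %in% colnames(metadata)) {
    groups <- stats::setNames(metadata[[config$contrast_column]], metadata$sample_id)
    groups <- groups[colnames(em$scores)]
    if (length(unique(groups[!is.na(groups)])) >= 2) {
      scaler <- fit_scaler(em)
      ct <- feature_contrast(apply_scaler(scaler, em), groups)
      ct_path <- file.path(config$out_dir, "feature_contrast.tsv")
      utils::write.table(ct, ct_path, sep = "\t", row.names = FALSE, quote = FALSE)
      emitted <- c(emitted, ct_path)
    }
  }
  manifest <- list(
    package = "pathwayDR",
    version = as.character(utils::packageVersion("pathwayDR")),
    seed = config$seed,
    config_hash = config_hash(config),
    condition = config$training$condition,
    n_features = nrow(em$scores),
    compounds = compound_entries,
    files = rel_checksums(config$out_dir, emitted))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated cohort to disk in the workflow's input formats
#'
#' Convenience wrapper around [simulate_cohort()] that writes the expression
#' matrix (GCT), gene sets (GMT), labels (CSV) and metadata (CSV) so the
#' full pipeline can run unmodified on simulated data. Ground truth is
#' returned, not written.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory.
#' @return list with the file \code{paths} and the \code{truth} object.
#' @export
write_simulated_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(spec)
  paths <- list(expression = file.path(dir, "expression.gct"),
                gmt = file.path(dir, "sets.gmt"),
                labels = file.path(dir, "labels.csv"),
                metadata = file.path(dir, "metadata.csv"))
  write_expression(cohort$expression, paths$expression, "gct")
  write_gmt(cohort$sets, paths$gmt)
  write_drug_response(cohort$labels, paths$labels)
  utils::write.csv(cohort$metadata, paths$metadata, row.names = FALSE, quote = FALSE)
  list(paths = paths, truth = cohort$truth, cohort = cohort)
}
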