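# Synthetic pharmacogenomic cohorts with known ground truth.
#
# The generator emulates the statistical shape of a CCLE/CTRP-style
# training resource: log2(TPM+1) bulk expression with latent per-sample
# pathway activities that shift member-gene expression, per-compound AUC
# labels driven linearly by a few driver pathways (larger AUC = more
# resistant), thinned labels, clinical metadata, and an additively
# batch-shifted held-out query cohort.

#' Specification for a synthetic pharmacogenomic cohort
#'
#' Defaults describe the cohort used throughout the package's own
#' evaluations: 200 training and 40 query samples, 300 gene sets of 15 genes
#' each plus 300 background genes, standard-normal latent pathway activities,
#' a 0.8 log2-unit expression loading per unit activity, and three compounds
#' each driven by one pathway with effect size 1.5 AUC units per unit
#' activity around a baseline AUC of 8.
#'
#' @param n_samples training-cohort size, default 200.
#' @param n_query query-cohort size (batch-shifted), default 40.
#' @param n_sets number of gene sets, default 300.
#' @param set_size genes per set, default 15.
#' @param background_genes genes belonging to no set, default 300.
#' @param loading expression shift (log2 units) per unit pathway activity,
#'   default 0.8.
#' @param expr_noise_sd observation noise sd on expression (log2 units),
#'   default 0.4.
#' @param auc_noise_sd observation noise sd on AUC, default 0.5.
#' @param missing_fraction fraction of labels thinned to missing, default 0.1.
#' @param batch_shift_sd sd of the per-gene additive batch shift applied to
#'   the query cohort, default 0.3.
#' @param compounds named list: compound -> list(drivers = set names,
#'   beta = effect sizes (AUC units per unit activity), beta0 = baseline
#'   AUC). NULL (default) builds \code{n_compounds} compounds with
#'   \code{drivers_per_compound} distinct driver sets each.
#' @param n_compounds,drivers_per_compound,beta,beta0 used to build the
#'   default compound roster when \code{compounds} is NULL.
#' @param glioma_fraction fraction of samples labelled "glioma" in the
#'   metadata, default 0.7.
#' @param seed master seed.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 200, n_query = 40, n_sets = 300,
                           set_size = 15, background_genes = 300,
                           loading = 0.8, expr_noise_sd = 0.4,
                           auc_noise_sd = 0.5, missing_fraction = 0.1,
                           batch_shift_sd = 0.3, compounds = NULL,
                           n_compounds = 3, drivers_per_compound = 1,
                           beta = 1.5, beta0 = 8, glioma_fraction = 0.7,
                           seed = 1) {
  assert_that(missing_fraction >= 0 && missing_fraction <= 1,
              "missing_fraction must be in [0,1]")
  assert_that(expr_noise_sd >= 0 && auc_noise_sd >= 0 && batch_shift_sd >= 0,
              "noise sds must be >= 0")
  set_names <- sprintf("SET_%03d", seq_len(n_sets))
  if (is.null(compounds)) {
    compounds <- lapply(seq_len(n_compounds), function(c) {
      drivers <- set_names[((c - 1) * drivers_per_compound) %% n_sets +
                             seq_len(drivers_per_compound)]
      list(drivers = drivers, beta = rep(beta, drivers_per_compound),
           beta0 = beta0)
    })
    names(compounds) <- sprintf("compound_%d", seq_len(n_compounds))
  }
  for (cmp in compounds) {
    assert_that(all(cmp$drivers %in% set_names),
                "driver references an undefined set: ",
                paste(setdiff(cmp$drivers, set_names), collapse = ", "))
    assert_that(length(cmp$beta) == length(cmp$drivers),
                "beta length must match driver count")
  }
  structure(list(n_samples = n_samples, n_query = n_query, n_sets = n_sets,
                 set_size = set_size, background_genes = background_genes,
                 loading = loading, expr_noise_sd = expr_noise_sd,
                 auc_noise_sd = auc_noise_sd,
                 missing_fraction = missing_fraction,
                 batch_shift_sd = batch_shift_sd, compounds = compounds,
                 set_names = set_names, glioma_fraction = glioma_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a pharmacogenomic cohort with known ground truth
#'
#' Expression is built as gene baseline + loading * activity of the gene's
#' set + Gaussian noise, clipped at 0 and tagged log2(TPM+1); each
#' compound's AUC is beta0 + sum over its driver sets of beta * activity +
#' noise; labels are thinned at the missing fraction (query samples keep all
#' labels so held-out performance is measurable); the query cohort receives
#' a per-gene additive batch shift. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with \code{expression} ([expression_matrix()], training plus
#'   query samples), \code{sets} ([gene_set_collection()]), \code{labels}
#'   ([drug_response_table()], training labels thinned), \code{metadata}
#'   (data.frame: sample_id, age, sex, mut_egfr, mut_idh1, disease_label,
#'   cohort), and \code{truth} (latent activities, full unthinned AUC,
#'   drivers, batch shift, cohort assignment).
#' @export
simulate_cohort <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  with_seed(spec$seed, {
    n_total <- spec$n_samples + spec$n_query
    n_set_genes <- spec$n_sets * spec$set_size
    n_genes <- n_set_genes + spec$background_genes
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    sample_ids <- c(sprintf("TRAIN_%04d", seq_len(spec$n_samples)),
                    sprintf("QUERY_%04d", seq_len(spec$n_query)))
    cohort <- rep(c("train", "query"), c(spec$n_samples, spec$n_query))
    # disjoint member-gene blocks per set; remaining genes are background
    membership <- rep(c(seq_len(spec$n_sets), NA),
                      c(rep(spec$set_size, spec$n_sets), spec$background_genes))
    sets <- split(gene_ids[!is.na(membership)], membership[!is.na(membership)])
    names(sets) <- spec$set_names
    activities <- matrix(stats::rnorm(n_total * spec$n_sets), n_total, spec$n_sets,
                         dimnames = list(sample_ids, spec$set_names))
    baseline <- stats::runif(n_genes, 1, 8)
    expr <- matrix(baseline, n_genes, n_total,
                   dimnames = list(gene_ids, sample_ids))
    in_set <- !is.na(membership)
    expr[in_set, ] <- expr[in_set, ] +
      spec$loading * t(activities[, membership[in_set], drop = FALSE])
    if (spec$expr_noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = spec$expr_noise_sd),
                            nrow(expr))
    }
    batch_shift <- stats::rnorm(n_genes, sd = spec$batch_shift_sd)
    expr[, cohort == "query"] <- expr[, cohort == "query"] + batch_shift
    expr[expr < 0] <- 0
    auc_full <- do.call(rbind, lapply(names(spec$compounds), function(cid) {
      cmp <- spec$compounds[[cid]]
      auc <- cmp$beta0 +
        as.numeric(activities[, cmp$drivers, drop = FALSE] %*% cmp$beta)
      if (spec$auc_noise_sd > 0) auc <- auc + stats::rnorm(n_total, sd = spec$auc_noise_sd)
      data.frame(sample_id = sample_ids, compound_id = cid, auc = auc)
    }))
    is_train_label <- auc_full$sample_id %in% sample_ids[cohort == "train"]
    drop <- is_train_label &
      stats::runif(nrow(auc_full)) < spec$missing_fraction
    labels <- drug_response_table(auc_full[!drop & is_train_label, , drop = FALSE])
    metadata <- data.frame(
      sample_id = sample_ids,
      age = round(stats::rnorm(n_total, 55, 12)),
      sex = sample(c("F", "M"), n_total, replace = TRUE),
      mut_egfr = stats::rbinom(n_total, 1, 0.3),
      mut_idh1 = stats::rbinom(n_total, 1, 0.2),
      disease_label = sample(c("glioma", "other"), n_total, replace = TRUE,
                             prob = c(spec$glioma_fraction, 1 - spec$glioma_fraction)),
      cohort = cohort)
    list(expression = expression_matrix(expr, scale = "log2tpm1"),
         sets = gene_set_collection(sets),
         labels = labels,
         metadata = metadata,
         truth = structure(list(activities = activities,
                                auc = drug_response_table(auc_full),
                                compounds = spec$compounds,
                                batch_shift = batch_shift,
                                cohort = stats::setNames(cohort, sample_ids),
                                spec = spec),
                           class = "ground_truth"))
  })
}

# coefficient of determination of predictions against observed values
r_squared <- function(pred, obs) {
  1 - mean((pred - obs)^2) / mean((obs - mean(obs))^2)
}

#' Score how well a trained bundle recovers the simulated ground truth
#'
#' Reports, for the bundle's compound: held-out R^2 on the query cohort
#' (which carries the simulated batch shift, so this is also the
#' batch-robustness figure), and, when an importance ranking is supplied,
#' driver recovery = the fraction of the compound's true driver sets ranked
#' inside the top \code{top_fraction} of features.
#'
#' @param bundle a trained \code{predictor_bundle}.
#' @param truth the \code{ground_truth} from [simulate_cohort()].
#' @param features enrichment features (raw scores) covering the query
#'   samples (and any others; only query columns are used).
#' @param ranking optional \code{importance_ranking} for driver recovery.
#' @param top_fraction importance cutoff for driver recovery, default 0.03.
#' @return list with \code{compound}, \code{heldout_r2}, \code{n_query}, and
#'   (with a ranking) \code{driver_recovery}.
#' @export
recovery_report <- function(bundle, truth, features, ranking = NULL,
                            top_fraction = 0.03) {
  cid <- bundle$compound_id
  assert_that(cid %in% names(truth$compounds),
              "compound '", cid, "' absent from the ground truth")
  v <- feature_values(features)
  query_ids <- names(truth$cohort)[truth$cohort == "query"]
  query_ids <- query_ids[query_ids %in% colnames(v)]
  assert_that(length(query_ids) > 0, "no query samples in the features")
  rec <- truth$auc[truth$auc$compound_id == cid, ]
  y <- stats::setNames(rec$auc, rec$sample_id)[query_ids]
  pred <- predict_bundle(bundle, v[, query_ids, drop = FALSE])
  out <- list(compound = cid, heldout_r2 = r_squared(pred, y),
              n_query = length(query_ids))
  if (!is.null(ranking)) {
    keep <- reduce_features(ranking, top_fraction)$retained
    drivers <- truth$compounds[[cid]]$drivers
    out$driver_recovery <- mean(drivers %in% keep)
  }
  out
}
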