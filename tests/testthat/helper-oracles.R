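# Independent oracles and shared fixtures for the test suite.

# Literal double-loop running-sum ssGSEA oracle: at every position i of the
# descending-ranked gene list, accumulate P_hit(i) - P_miss(i) from scratch.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  ids <- names(expr)
  n <- length(expr)
  o <- order(-expr, ids, method = "radix")
  ranked_in_set <- ids[o] %in% gene_set
  w <- (n:1)^alpha
  es <- 0
  for (i in seq_len(n)) {
    p_hit <- sum(w[seq_len(i)][ranked_in_set[seq_len(i)]]) / sum(w[ranked_in_set])
    p_miss <- sum(!ranked_in_set[seq_len(i)]) / sum(!ranked_in_set)
    es <- es + p_hit - p_miss
  }
  es
}

random_ssgsea_instance <- function() {
  n <- sample(4:60, 1)
  expr <- stats::setNames(round(stats::runif(n, 0, 12), 3),
                          sprintf("g%04d", sample.int(5000, n)))
  size <- sample(seq_len(min(20, n - 1)), 1)
  list(expr = expr, set = sample(names(expr), size),
       alpha = sample(c(0, 0.25, 0.75, 1), 1))
}

# small named expression matrix fixture
tiny_expr <- function(genes = 20, samples = 6, seed = 1) {
  with_seed_local(seed, {
    v <- matrix(round(stats::runif(genes * samples, 0, 10), 3), genes, samples,
                dimnames = list(sprintf("g%03d", seq_len(genes)),
                                sprintf("s%02d", seq_len(samples))))
    expression_matrix(v, "log2tpm1")
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# shared small trained fixture, built once per test run (training is the
# expensive step; several test files reuse it)
.fixtures <- new.env(parent = emptyenv())

small_trained_task <- function() {
  if (!is.null(.fixtures$task)) return(.fixtures$task)
  spec <- synthetic_spec(n_samples = 60, n_query = 20, n_sets = 30,
                         set_size = 8, background_genes = 60,
                         n_compounds = 2, missing_fraction = 0.1, seed = 101)
  cohort <- simulate_cohort(spec)
  em <- ssgsea_matrix(cohort$expression, cohort$sets)
  cfg <- training_config(n_trials = 2, seed = 11,
                         families = c("gbm", "random_forest", "knn_uniform"))
  bundle <- train_predictor(em, cohort$labels, "compound_1", cfg)
  .fixtures$task <- list(spec = spec, cohort = cohort, em = em, cfg = cfg,
                         bundle = bundle)
  .fixtures$task
}

# labels of one compound as a named vector over all simulated samples
truth_auc <- function(cohort, compound) {
  rec <- cohort$truth$auc[cohort$truth$auc$compound_id == compound, ]
  stats::setNames(rec$auc, rec$sample_id)
}
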