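# pathwayDR

Pathway-feature drug response prediction with weighted ensembles.

## What it does and who it is for

Pharmacogenomic screens such as CCLE/CTRP pair bulk gene expression of
cancer cell lines with per-compound dose–response AUC values (larger AUC =
more resistant). pathwayDR turns such data into per-compound predictors
that can score new samples — e.g. patient-derived tumour profiles — for
expected drug sensitivity, and provides the downstream tooling to evaluate
and interpret those predictions. It is aimed at computational biologists
building drug-sensitivity models from transcriptomes.

The workflow:

1. **Features.** Expression (log2(TPM+1), GCT/TSV) is converted into
   single-sample gene-set enrichment (ssGSEA) scores over a gene-set
   collection (GMT), then min–max scaled to [0, 1] with training-cohort
   statistics. For one sample with genes ranked by expression (rank weight
   w = N − i + 1 at position i), the enrichment score of a set S is

   ES = Σᵢ [P_hit(i) − P_miss(i)],  P_hit(i) = Σ_{g∈S, pos(g)≤i} w_g^α / Σ_{g∈S} w_g^α,
   P_miss(i) = |{g∉S, pos(g)≤i}| / (N − |S|).

2. **Training.** Each compound is trained independently across nine base
   learner families (three gradient-boosted-tree variants, two
   single-hidden-layer neural nets, random forest, extremely randomized
   trees, uniform and distance-weighted kNN) with random hyperparameter
   search, scored by repeated k-fold out-of-fold (OOF) mean squared error.
   The *validation score* is the negative OOF MSE (closer to zero is
   better).

3. **Stack-two weighted ensemble.** A convex combination of the base
   families fitted on the OOF predictions by (bagged) greedy forward
   selection with replacement. Its OOF MSE never exceeds the best single
   family's — asserted on every fit.

4. **Feature reduction.** Permutation importance against the deployed
   ensemble ranks all features; the top 20/10/3% (RF20/RF10/RF3) are
   retained and the models retrained — the main defence against the
   features-outnumber-samples regime.

5. **Evaluation.** Held-out regression of measured log2(IC50) on predicted
   AUC, PCA/t-SNE embeddings of response profiles, group-wise feature
   contrasts, and a synthetic cohort generator with known ground truth for
   end-to-end validation.

## Worked example

```r
library(pathwayDR)

# simulate a small pharmacogenomic cohort with one pathway-driven compound
spec <- synthetic_spec(n_samples = 80, n_query = 20, n_sets = 50, set_size = 10,
                       background_genes = 100, n_compounds = 1, seed = 42)
cohort <- simulate_cohort(spec)

# ssGSEA features and per-compound training (desk-scale search)
em  <- ssgsea_matrix(cohort$expression, cohort$sets)
cfg <- training_config(n_trials = 4, seed = 1)
bundle <- train_predictor(em, cohort$labels, "compound_1", cfg)
round(bundle$provenance$validation_scores, 3)
#>           gbm        gbm_xt     gbm_large          nnet     nnet_wide
#>        -1.001        -0.925        -0.745        -1.476        -1.452
#> random_forest   extra_trees   knn_uniform  knn_distance      ensemble
#>        -1.613        -1.284        -2.331        -2.564        -0.745
```

The ensemble validation score (−0.745) matches the best family here
(`gbm_large`; the boosting families dominate, the kNN families trail — the
usual picture on enrichment features). Reduce to the top 3% of features and
retrain:

```r
pairs   <- align_training_pairs(em, cohort$labels, "compound_1")
ranking <- permutation_importance(bundle, em$scores[, pairs$sample_ids],
                                  pairs$auc, n_shuffle_sets = 5, seed = 1)
head(as.data.frame(ranking), 3)
#>   feature importance  dispersion      p_value rank
#> 1 SET_001 4.14356264 0.472197466 1.989286e-05    1
#> 2 SET_004 0.01356781 0.000517006 2.525132e-07    2
#> 3 SET_045 0.01201647 0.001848622 6.514543e-05    3

plan <- reduce_features(ranking, 0.03)   # RF3
rf3  <- retrain_reduced(em, cohort$labels, "compound_1", plan, cfg)
round(rf3$provenance$validation_scores[["ensemble"]], 3)
#> [1] -0.41

recovery_report(rf3, cohort$truth, em, ranking = ranking)[c("heldout_r2", "driver_recovery")]
#> $heldout_r2
#> [1] 0.8012166
#> $driver_recovery
#> [1] 1
```

The planted driver pathway (`SET_001`) ranks first with a dominant
importance (4.14 vs 0.014 for the runner-up); RF3 retraining improves the
validation score from −0.745 to −0.410; the reduced model reaches R² = 0.80
on the batch-shifted held-out cohort and the top-3% feature list contains
the true driver (recovery = 1).

The same pipeline runs from files (GCT + GMT + labels CSV) via
`run_workflow(run_config(...))` or the CLI's `run-all`, producing
per-compound bundle directories, importance rankings, embeddings, contrast
tables and a `manifest.json` with seeds, a config hash and per-file
checksums.

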