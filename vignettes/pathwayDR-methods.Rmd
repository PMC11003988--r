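---
title: "Methods: pathway-feature drug response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-feature drug response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

pathwayDR predicts compound sensitivity — the area under the dose–response
curve (AUC), with larger values meaning greater resistance — for cancer
samples profiled by bulk RNA-seq. The workflow has four stages:

1. **Feature engineering.** Expression on the log2(TPM+1) scale is reduced
   to single-sample gene-set enrichment (ssGSEA) scores over a gene-set
   collection (GMT), one score per set per sample, then min–max scaled to
   [0, 1] using statistics learned from the training cohort only.
2. **Per-compound training.** Each compound is trained independently: nine
   base learner families are tuned by random hyperparameter search, scored
   by repeated k-fold out-of-fold (OOF) mean squared error.
3. **Stack-two weighted ensemble.** A convex combination of the base
   families is fitted on their OOF predictions by greedy forward selection
   with replacement, with bagging of the selection as overfitting control.
4. **Feature reduction and downstream evaluation.** Permutation importance
   against the deployed ensemble ranks the features; the top 20/10/3%
   (RF20/RF10/RF3) are retained and the models retrained. Evaluation tools
   cover measured-potency regression (log2 IC50 vs predicted AUC), 2-D
   embeddings of response profiles (PCA, exact t-SNE), and group-wise
   feature contrasts.

## The ssGSEA score

For one sample, genes are ranked by expression, descending; expression ties
are broken by gene ID (lexicographic, C locale) so scores are deterministic.
The gene at position $i$ of $N$ receives the rank weight $w = N - i + 1$.
For a gene set $S$ the enrichment score is

$$\mathrm{ES} = \sum_{i=1}^{N} \left[ P_{\mathrm{hit}}(i) - P_{\mathrm{miss}}(i) \right],
\qquad
P_{\mathrm{hit}}(i) = \frac{\sum_{g \in S,\ \mathrm{pos}(g) \le i} w_g^{\alpha}}{\sum_{g \in S} w_g^{\alpha}},
\qquad
P_{\mathrm{miss}}(i) = \frac{\left|\{ g \notin S,\ \mathrm{pos}(g) \le i \}\right|}{N - |S|}.$$

Exchanging the order of summation collapses the running sum to a closed
form,

$$\mathrm{ES} = \frac{\sum_{g \in S} w_g^{1+\alpha}}{\sum_{g \in S} w_g^{\alpha}}
 - \frac{\sum_{g \notin S} w_g}{N - |S|},$$

which the engine evaluates with three matrix products per cohort. The test
suite holds the literal double-loop running-sum oracle and checks exact
agreement on hundreds of random instances.

Choices worth noting:

* **Rank weights, not raw expression** ($w = N - i + 1$): robust to the
  expression scale and the standard single-sample convention. At
  $\alpha = 0$ the score reduces to an unweighted ECDF difference and is
  invariant to adding a constant to all expression values.
* **`alpha = 0.75`** by default (configurable), the common single-sample
  enrichment convention.
* **Set-size bounds `c(5, 2000)`** after intersecting each set with the
  expression genes: smaller sets give noisy, degenerate scores; a set
  covering all genes has an undefined out-of-set ECDF and is an error.
* **No cross-collection ES renormalization**: the [0, 1] min–max scaling of
  the feature matrix supersedes it.
* Gene identifiers are matched exactly (case-sensitive, no alias mapping).

## Scaling and metadata

`fit_scaler()` learns per-feature minima and maxima on the training cohort;
`apply_scaler()` maps any cohort through the same affine transform and clips
query values to [0, 1]. Clipping keeps query features inside the training
support without leaking query statistics into the transform. Features that
are constant in training are flagged and mapped to 0. Applying a fitted
scaler to its own output is a no-op (scaled matrices are tagged), so
pipelines may scale defensively.

The optional "Metadata+" variant appends clinical columns: numeric columns
are median-imputed and min–max scaled with the same fit/apply contract;
categorical columns are one-hot encoded over the training levels, with
missing values yielding all-zero indicator blocks. Metadata features carry a
reserved `meta:` prefix. The "Glioma+" variant instead restricts the
training cohort to one `disease_label` before training.

## Per-compound training

Nine base families are searched (`learner_roster()`), in a fixed roster
order that also serves as the deterministic tie-break order everywhere:

| family | implementation | randomization axis |
|---|---|---|
| `gbm` | xgboost, hist | column subsample per tree |
| `gbm_xt` | xgboost, hist | column subsample per node |
| `gbm_large` | xgboost, hist | more rounds, lower learning rate |
| `nnet`, `nnet_wide` | single-hidden-layer nets | width/decay ranges |
| `random_forest` | ranger | bootstrap + mtry |
| `extra_trees` | ranger (`splitrule = "extratrees"`) | random split points |
| `knn_uniform`, `knn_distance` | exact kNN regressor | uniform vs 1/d weights |

The three boosted-tree spaces are deliberately balanced — same core
capacity, different randomization — so that the ensemble's weight allocation
among them is driven by genuine performance differences rather than by one
variant having a systematically stronger search space.

Each family draws `n_trials` hyperparameter settings from its documented
space; each setting is scored by `repeats` × `folds`-fold cross-validation
OOF mean squared error, and the best trial's fold models are refitted for
serving. Fold assignments are shared across families so the OOF prediction
matrix is stackable. The validation score is the negative OOF MSE — closer
to zero is better. All seeds (folds, draws, fits, permutations) derive from
one master seed via a label hash, so any compound can be recomputed in
isolation, in any order, with identical results; tree and net fits are
single-threaded, making runs reproducible on a fixed platform.

Desk-scale defaults are `n_trials = 16`, `repeats = 1`; the full-scale
configuration (`n_trials = 512`, `repeats = 3`) is an ordinary override and
changes nothing structurally. OOF predictions across repeats are aggregated
per sample by the mean. The validation score is computed on OOF predictions
(not an inner holdout), and the provenance records this.

## The weighted ensemble

Greedy forward selection with replacement over the base families' OOF
prediction vectors: starting from the empty ensemble, repeatedly add the
model whose inclusion minimizes the OOF MSE of the running average, up to a
budget of 100 picks; the best ensemble along the trace is returned, and
normalized pick counts are the weights. Because the first pick is the
single best model, the returned ensemble's OOF MSE never exceeds the best
single model's — an invariant asserted on every fit.

Plain greedy selection can overfit the weight allocation when several
near-equal families differ only by OOF noise (with `repeats = 1` the OOF
estimates are noisy). The default therefore bags the selection: greedy runs
on 50 random half-subsamples of the OOF rows and the weight vectors are
averaged. If the bagged weights would violate the never-worse invariant on
the full OOF data, the plain greedy solution is used instead. The level-2
model is a convex combination only — no level-2 learner — which keeps the
guarantee and the "weighted ensemble" semantics.

Serving predictions average each family's fold models, then combine
families by weight.

## Permutation importance and feature reduction

Importance of a feature is the drop in the ensemble's score (negative MSE)
when that feature's column is permuted, averaged over `n_shuffle_sets`
seeded permutations, on a subsample of at most `subsample_size` rows
(default 5000, capped at the cohort size). The one-sided p-value comes from
a t-test on the per-shuffle-set drops (null: importance ≤ 0) — the
convention of tabular auto-ML importance reports, and the only estimator
that can resolve p < 0.05 from 10 shuffle sets. Importance is computed
against the deployed ensemble, not per base model, because the ranking must
serve the bundle actually used downstream.

`reduce_features()` retains the top `max(1, floor(fraction * F))` features
(floor with a minimum of one; the presets 0.20/0.10/0.03 are the
RF20/RF10/RF3 conditions), and `retrain_reduced()` reruns the full
training procedure — including a fresh hyperparameter search — on the
restricted columns, recording the fraction in provenance. Retraining with
fraction 1.0 and the same seed reproduces the original run exactly (the
feature subset is applied in the feature matrix's canonical order).

## Downstream evaluation

* `regress_ic50_vs_auc()`: ordinary least squares of log2-transformed
  measured IC50 on predicted AUC; reports slope, intercept and R².
  A constant predictor is flagged and reported as R² = 0.
* `response_embedding()`: PCA (exact, deterministic) or t-SNE. No t-SNE
  implementation was available among the package's dependencies, so an
  exact $O(n^2)$ t-SNE with per-point perplexity calibration, early
  exaggeration and momentum is implemented in `R/tsne.R`; it is
  deterministic under a fixed seed and intended for the package's typical
  item counts (hundreds of compounds or patients). Perplexity defaults to
  30 capped at $(n-1)/3$. Columns are standardized before embedding by
  default.
* `feature_contrast()`: per group and feature, the standardized one-vs-rest
  mean difference (difference of means over the pooled standard deviation,
  variance floor $10^{-8}$). This statistic is a package convention chosen
  for interpretability — a descriptive ranking, not a hypothesis test, and
  not a claim about any biological phenotype.

## The synthetic cohort generator

`synthetic_spec()` / `simulate_cohort()` generate cohorts with known ground
truth so every stage is testable without external data:

* latent pathway activities: one standard normal draw per sample × set;
* expression: per-gene baseline Uniform(1, 8) on the log2(TPM+1) scale,
  plus `loading` (default 0.8 log2 units per unit activity) for member
  genes, plus Gaussian noise (default sd 0.4), clipped at 0;
* sets: disjoint member-gene blocks (default 300 sets × 15 genes) plus
  background genes (default 300);
* labels: $\mathrm{AUC}_c = \beta_{0,c} + \sum_k \beta_{c,k}\,a_k +
  \varepsilon$ with default baseline 8, effect 1.5 AUC units per unit
  activity and noise sd 0.5, thinned to missing at rate 0.1 (training
  cohort only);
* a query cohort (default 40 samples) receives a per-gene additive batch
  shift (default sd 0.3) emulating a train/query technical offset;
* metadata: age, sex, two mutation flags, a disease label (default 70%
  "glioma"), and the cohort assignment.

Defaults were chosen once as a plausible desk-scale pharmacogenomic regime
(cohort of a few hundred samples, feature count exceeding the sample count,
signal-to-noise giving held-out R² around 0.6–0.8 for a strong compound).
What the generator does **not** emulate: gene–gene correlation beyond the
set-driven structure, dose–response curve shapes (AUC is generated
directly), non-linear pathway interactions, and realistic CTRP AUC units.
Passing tests therefore demonstrate the machinery's correctness and the
qualitative phenomena (ensemble gains, reduction gains, driver recovery),
not performance on real cohorts.

## Problem sizes used by the test suite

The acceptance-style tests run at desk scale, chosen so the whole suite
fits comfortably on one CPU: ensemble-superiority and feature-reduction
replications use 10 seeded cohorts each (200 and 120 training samples, 300
gene sets, 5-fold OOF, 6 search trials per family; importance with 5
shuffle sets); the ensemble-superiority task uses a compound driven by 8
pathways with geometrically decaying effects ($\beta_k = 1.5 \cdot
0.85^k$) and a 150-sample held-out cohort. A single-pathway compound is a
degenerate probe for ensemble gains — every competent learner converges to
the same one-dimensional monotone fit and their errors correlate above
0.9 — whereas multi-pathway response surfaces let the families err in
different places, which is exactly the regime the weighted ensemble is
for. All statistical thresholds in those tests were fixed a priori.

## Known limitations

* The ensemble's never-worse guarantee holds on the OOF data its weights
  are fitted to. On held-out cohorts it typically matches or beats almost
  every family, but it can trail the *post hoc* best single family by a
  small margin (a selection effect: the minimum over nine noisy held-out
  MSE estimates is biased low, and no weighting fitted on OOF data can
  dominate it uniformly). The test suite measures this win fraction on
  seeded replicates of the multi-pathway task; when the ensemble loses to
  the lucky best family, the margin is small relative to the MSE.
* Exact gene-ID matching; symbol/alias reconciliation is out of scope.
* The kNN families use exact distances; beyond ~10^4 training samples they
  would need an approximate neighbour index.
* `nnet` (single hidden layer, BFGS) underperforms gradient boosting on
  high-dimensional enrichment features at desk scale; it is retained for
  roster faithfulness and diversity, not as a strong baseline.
* Determinism is platform-conditional: identical results require the same
  BLAS, compiler and single-threaded execution.
* The Glioma+ trial roster extensions (symmetric-tree boosting variants)
  are deliberately not included: restricting the cohort while enlarging
  the roster encourages overfitting to a smaller training set.
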