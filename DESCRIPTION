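Package: pathwayDR
Title: Pathway-Feature Drug Response Prediction with Weighted Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts compound sensitivity (area under the dose-response
    curve, AUC) of cancer samples from bulk gene expression. Expression on the
    log2(TPM+1) scale is converted into single-sample gene-set enrichment
    (ssGSEA) scores over a gene-set collection, min-max scaled to [0,1], and
    used as features for per-compound regression across nine base learner
    families (boosted trees, nearest neighbours, feed-forward neural networks,
    random forest, extremely randomized trees) with random hyperparameter
    search and repeated k-fold out-of-fold scoring. A greedy stack-two
    weighted ensemble combines the base models, permutation feature importance
    drives top-percent feature reduction and retraining, and downstream tools
    provide IC50-vs-prediction regression, PCA/t-SNE response-profile
    embeddings, and group-wise feature contrasts. A synthetic pharmacogenomic
    cohort generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
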