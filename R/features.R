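# Feature engineering: single-sample gene-set enrichment (ssGSEA) scores,
# [0,1] min-max scaling with a strict fit/apply contract, and optional
# clinical-metadata feature augmentation.

# Positions of genes in the descending-expression ranking, ties broken by
# gene ID lexicographic order (C locale) for determinism.
rank_positions <- function(values, ids) {
  o <- order(-values, ids, method = "radix")
  pos <- integer(length(values))
  pos[o] <- seq_along(values)
  pos
}

#' Single-sample gene-set enrichment score
#'
#' Genes are ranked by expression (descending; ties broken by gene ID).
#' The rank weight of the gene at position i is w = N - i + 1. The score is
#' the sum over positions of the difference between the weighted in-set
#' cumulative distribution P_hit(i) = sum of w^alpha over in-set genes at
#' positions <= i, normalized by the in-set total, and the unweighted
#' out-of-set cumulative distribution P_miss(i):
#' ES = sum_i [P_hit(i) - P_miss(i)].
#'
#' The implementation evaluates the algebraically equivalent closed form
#' ES = sum_{g in S} w_g^(1+alpha) / sum_{g in S} w_g^alpha
#'      - sum_{g notin S} w_g / (N - |S|),
#' which follows from exchanging the order of the double summation.
#'
#' @param expr named numeric vector of expression values for one sample
#'   (all genes, not just the set).
#' @param gene_set character vector of gene IDs.
#' @param alpha rank-weight exponent (>= 0); 0 gives unweighted ranks,
#'   0.75 is the package default elsewhere.
#' @return the enrichment score (ES), a single number.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.75) {
  ids <- names(expr)
  n <- length(expr)
  assert_that(n >= 2, "need at least 2 genes")
  assert_that(!is.null(ids) && !anyDuplicated(ids), "expr must be named with unique gene IDs")
  assert_that(all(is.finite(expr)), "non-finite expression value")
  assert_that(alpha >= 0, "alpha must be >= 0")
  in_set <- ids %in% gene_set
  assert_that(any(in_set), "gene set does not intersect the expression genes")
  assert_that(!all(in_set), "gene set covers all genes; out-of-set ECDF undefined")
  w <- (n - rank_positions(expr, ids) + 1)
  wa <- w^alpha
  sum(w[in_set] * wa[in_set]) / sum(wa[in_set]) -
    sum(w[!in_set]) / sum(!in_set)
}

#' ssGSEA score matrix for a gene-set collection
#'
#' Computes one enrichment score per retained gene set per sample. Each set is
#' first intersected with the expression genes; sets whose post-intersection
#' size falls outside \code{bounds} are dropped (reported via a message).
#' Columns are computed independently per sample.
#'
#' @param expr an [expression_matrix()] on the log2(TPM+1) scale.
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent, default 0.75 (common ssGSEA
#'   convention).
#' @param bounds length-2 integer vector, (min, max) retained set size after
#'   intersection; default c(5, 2000).
#' @return an object of class \code{enrichment_matrix}: list with
#'   \code{scores} (sets x samples matrix), \code{alpha}, \code{bounds},
#'   \code{dropped} (names of dropped sets).
#' @export
ssgsea_matrix <- function(expr, sets, alpha = 0.75, bounds = c(5, 2000)) {
  assert_that(inherits(expr, "expression_matrix"), "expr must be an expression_matrix")
  assert_that(expr$scale == "log2tpm1",
              "expression must be on the log2(TPM+1) scale; run log_transform() first")
  assert_that(inherits(sets, "gene_set_collection"), "sets must be a gene_set_collection")
  v <- expr$values
  ids <- rownames(v)
  n <- nrow(v)
  inter <- lapply(sets$sets, function(g) g[g %in% ids])
  sizes <- lengths(inter)
  keep <- sizes >= bounds[1] & sizes <= bounds[2] & sizes < n
  if (any(!keep)) {
    message(sprintf("ssgsea_matrix: dropping %d/%d set(s) outside size bounds [%d, %d] after intersection",
                    sum(!keep), length(keep), bounds[1], bounds[2]))
  }
  assert_that(any(keep), "all gene sets dropped by size bounds")
  inter <- inter[keep]
  sizes <- sizes[keep]
  k <- length(inter)
  # membership matrix genes x sets (0/1)
  m <- matrix(0, n, k)
  for (j in seq_len(k)) m[match(inter[[j]], ids), j] <- 1
  ns <- ncol(v)
  u1 <- matrix(0, n, ns)  # w^(1+alpha) per gene per sample
  u2 <- matrix(0, n, ns)  # w^alpha
  u3 <- matrix(0, n, ns)  # w
  for (s in seq_len(ns)) {
    w <- n - rank_positions(v[, s], ids) + 1
    u3[, s] <- w
    u2[, s] <- w^alpha
    u1[, s] <- w * u2[, s]
  }
  tm <- t(m)
  hit <- (tm %*% u1) / (tm %*% u2)
  miss <- (matrix(colSums(u3), k, ns, byrow = TRUE) - tm %*% u3) / (n - sizes)
  scores <- hit - miss
  dimnames(scores) <- list(names(inter), colnames(v))
  structure(list(scores = scores, alpha = alpha, bounds = bounds,
                 set_sizes = stats::setNames(sizes, names(inter)),
                 dropped = names(keep)[!keep] %||% character()),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d sets x %d samples (alpha = %g)\n",
              nrow(x$scores), ncol(x$scores), x$alpha))
  invisible(x)
}

#' @export
dim.enrichment_matrix <- function(x) dim(x$scores)

# Accept an enrichment_matrix or a plain features x samples matrix.
feature_values <- function(x) {
  if (inherits(x, "enrichment_matrix")) x$scores else {
    assert_that(is.matrix(x) && !is.null(rownames(x)),
                "features must be an enrichment_matrix or a named matrix")
    x
  }
}

#' Fit a per-feature [0,1] min-max scaler on training features
#'
#' Learns each feature's minimum and maximum from the training enrichment
#' scores. Applying the fitted scaler maps training values into [0,1]
#' exactly; query values outside the training range are clipped to [0,1] so
#' that no query statistics leak into the scaling. Degenerate features
#' (max == min in training) are flagged and map to 0.
#'
#' @param x an \code{enrichment_matrix} or a features x samples numeric
#'   matrix with feature rownames.
#' @return an object of class \code{minmax_scaler}.
#' @export
fit_scaler <- function(x) {
  v <- feature_values(x)
  mins <- apply(v, 1, min)
  maxs <- apply(v, 1, max)
  structure(list(feature_names = rownames(v), min = mins, max = maxs,
                 degenerate = maxs == mins, clip = TRUE),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param state a \code{minmax_scaler} from [fit_scaler()].
#' @param x features to scale (same orientation and feature names as at fit
#'   time; sample columns may differ).
#' @return features x samples matrix of scaled values in [0,1].
#' @export
apply_scaler <- function(state, x) {
  assert_that(inherits(state, "minmax_scaler"), "state must be a minmax_scaler")
  # idempotence: output is tagged, and already-scaled input passes through
  if (isTRUE(attr(x, "minmax_scaled"))) return(x)
  v <- feature_values(x)
  extra <- setdiff(rownames(v), state$feature_names)
  missing <- setdiff(state$feature_names, rownames(v))
  assert_that(length(extra) == 0 && length(missing) == 0,
              "feature-name mismatch; missing: [",
              paste(missing, collapse = ", "), "], unexpected: [",
              paste(extra, collapse = ", "), "]")
  v <- v[state$feature_names, , drop = FALSE]
  rng <- state$max - state$min
  rng[state$degenerate] <- 1  # avoid 0/0; result overwritten below
  out <- (v - state$min) / rng
  out[state$degenerate, ] <- 0
  if (state$clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "minmax_scaled") <- TRUE
  out
}

#' Fit a metadata feature encoder
#'
#' Numeric columns are min-max scaled (same fit/apply and clipping contract
#' as the enrichment features); missing numeric values are imputed with the
#' training median. Categorical columns are one-hot encoded over the training
#' levels; samples with a missing value get an all-zero indicator block.
#'
#' @param metadata data.frame with a \code{sample_id} column (training
#'   samples).
#' @param columns character vector of metadata columns to encode.
#' @return an object of class \code{metadata_encoder}.
#' @export
fit_metadata_encoder <- function(metadata, columns) {
  absent <- setdiff(columns, colnames(metadata))
  assert_that(length(absent) == 0,
              "metadata column(s) not found: ", paste(absent, collapse = ", "))
  enc <- lapply(columns, function(col) {
    v <- metadata[[col]]
    if (is.numeric(v)) {
      med <- stats::median(v, na.rm = TRUE)
      filled <- ifelse(is.na(v), med, v)
      list(type = "numeric", median = med, min = min(filled), max = max(filled))
    } else {
      list(type = "categorical", levels = sort(unique(as.character(v[!is.na(v)]))))
    }
  })
  names(enc) <- columns
  structure(list(columns = enc), class = "metadata_encoder")
}

apply_metadata_encoder <- function(encoder, metadata, sample_ids) {
  idx <- match(sample_ids, metadata$sample_id)
  blocks <- lapply(names(encoder$columns), function(col) {
    e <- encoder$columns[[col]]
    v <- if (col %in% colnames(metadata)) metadata[[col]][idx] else rep(NA, length(idx))
    if (e$type == "numeric") {
      v <- as.numeric(v)
      v[is.na(v)] <- e$median
      rng <- e$max - e$min
      out <- if (rng == 0) rep(0, length(v)) else pmin(pmax((v - e$min) / rng, 0), 1)
      matrix(out, nrow = 1, dimnames = list(paste0("meta:", col), sample_ids))
    } else {
      v <- as.character(v)
      block <- matrix(0, length(e$levels), length(v),
                      dimnames = list(paste0("meta:", col, "=", e$levels), sample_ids))
      for (i in seq_along(v)) {
        if (!is.na(v[i]) && v[i] %in% e$levels) block[paste0("meta:", col, "=", v[i]), i] <- 1
      }
      block
    }
  })
  do.call(rbind, blocks)
}

#' Append encoded clinical metadata to a feature matrix
#'
#' Implements the "Metadata+" workflow variant: encoded metadata columns
#' (prefixed \code{meta:}) are appended below the enrichment features.
#' Pass \code{encoder = NULL} to fit on the given metadata (training); pass a
#' fitted encoder to apply the training encoding to query samples.
#'
#' @param features features x samples matrix (or \code{enrichment_matrix})
#'   of scaled enrichment scores.
#' @param metadata data.frame with \code{sample_id} plus the named columns.
#' @param columns metadata columns to encode.
#' @param encoder optional fitted \code{metadata_encoder}.
#' @return features x samples matrix with the metadata rows appended; the
#'   fitted encoder is attached as attribute \code{"encoder"}.
#' @export
augment_with_metadata <- function(features, metadata, columns, encoder = NULL) {
  v <- feature_values(features)
  if (is.null(encoder)) {
    train_meta <- metadata[metadata$sample_id %in% colnames(v), , drop = FALSE]
    encoder <- fit_metadata_encoder(train_meta, columns)
  }
  block <- apply_metadata_encoder(encoder, metadata, colnames(v))
  out <- rbind(v, block)
  attr(out, "encoder") <- encoder
  out
}
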