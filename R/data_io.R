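# Readers/writers for the formats the workflow touches (GCT 1.2, TSV, GMT,
# long-format label CSV, metadata CSV) and assembly of aligned training pairs.

#' Construct an expression matrix
#'
#' The central expression container: a genes x samples numeric matrix tagged
#' with its scale. Downstream feature building requires the
#' \code{"log2tpm1"} scale (log2(TPM+1), the CCLE convention); raw TPM input
#' is tagged \code{"tpm"} and must pass through [log_transform()] first.
#'
#' @param values numeric matrix (genes x samples) with unique, non-empty
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param scale either \code{"log2tpm1"} or \code{"tpm"}.
#' @return an object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, scale = c("log2tpm1", "tpm")) {
  scale <- match.arg(scale)
  assert_that(is.matrix(values) && is.numeric(values),
              "expression values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "expression matrix needs gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate gene IDs")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample IDs")
  assert_that(all(is.finite(values)), "expression values must be finite")
  if (scale == "tpm") {
    assert_that(all(values >= 0), "TPM values must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# collapse duplicate gene rows to the row with the highest mean expression
collapse_duplicate_genes <- function(values, ids) {
  if (!anyDuplicated(ids)) {
    rownames(values) <- ids
    return(values)
  }
  means <- rowMeans(values)
  # order by descending mean so the first occurrence of each ID is the winner
  o <- order(-means)
  keep <- o[!duplicated(ids[o])]
  keep <- sort(keep)  # preserve original file order among winners
  warning(sprintf("%d duplicated gene ID(s) collapsed to the max-mean row",
                  sum(duplicated(ids))), call. = FALSE)
  values <- values[keep, , drop = FALSE]
  rownames(values) <- ids[keep]
  values
}

#' Read an expression matrix from GCT 1.2 or TSV
#'
#' The GCT dialect expects a \code{#1.2} version line, a dimensions line
#' (\code{n_genes<TAB>n_samples}), then a header row starting
#' \code{Name<TAB>Description} followed by sample IDs. TSV expects a header
#' row (first column gene ID, remaining columns samples). Duplicate gene rows
#' are collapsed to the row with the highest mean expression, with a warning.
#'
#' @param path file path.
#' @param format \code{"gct"} or \code{"tsv"}.
#' @param scale scale tag to attach, \code{"log2tpm1"} (default) or
#'   \code{"tpm"}.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("gct", "tsv"),
                            scale = c("log2tpm1", "tpm")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  assert_that(file.exists(path), "expression file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    assert_that(length(lines) >= 3, "GCT file too short: ", path)
    assert_that(trimws(lines[1]) == "#1.2",
                "malformed GCT: first line must be '#1.2', got '", lines[1], "'")
    dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    assert_that(length(dims) >= 2 && !anyNA(suppressWarnings(as.integer(dims[1:2]))),
                "malformed GCT: dimensions line '", lines[2], "'")
    ng <- as.integer(dims[1]); ns <- as.integer(dims[2])
    header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
    assert_that(length(header) == ns + 2,
                "malformed GCT: header has ", length(header) - 2,
                " sample columns, dimensions line declares ", ns)
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    assert_that(length(body) == ng,
                "GCT body has ", length(body), " data rows, dimensions line declares ", ng)
    cells <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(cells, `[[`, "", 1)
    vals <- matrix(NA_real_, ng, ns)
    for (i in seq_len(ng)) {
      row <- cells[[i]]
      assert_that(length(row) == ns + 2,
                  "GCT row ", i, " has ", length(row) - 2, " values, expected ", ns)
      v <- suppressWarnings(as.numeric(row[-(1:2)]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop_pdr("non-numeric cell at data row ", i, ", sample column ", bad,
                 ": '", row[bad + 2], "'")
      }
      vals[i, ] <- v
    }
    colnames(vals) <- header[-(1:2)]
    vals <- collapse_duplicate_genes(vals, ids)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    assert_that(ncol(df) >= 2, "TSV needs a gene column plus >= 1 sample column")
    ids <- df[[1]]
    vals <- matrix(NA_real_, nrow(df), ncol(df) - 1)
    for (j in seq_len(ncol(df) - 1)) {
      v <- suppressWarnings(as.numeric(df[[j + 1]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop_pdr("non-numeric cell at data row ", bad, ", column '",
                 colnames(df)[j + 1], "': '", df[[j + 1]][bad], "'")
      }
      vals[, j] <- v
    }
    colnames(vals) <- colnames(df)[-1]
    vals <- collapse_duplicate_genes(vals, ids)
  }
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to GCT 1.2 or TSV
#'
#' Lossless counterpart of [read_expression()]: values are written at full
#' double precision.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param format \code{"gct"} or \code{"tsv"}.
#' @export
write_expression <- function(x, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  v <- x$values
  val_chr <- matrix(num_chr(v), nrow(v), ncol(v))
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i) {
                 paste(c(rownames(v)[i], "na", val_chr[i, ]), collapse = "\t")
               }, ""))
  } else {
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i) {
                 paste(c(rownames(v)[i], val_chr[i, ]), collapse = "\t")
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert TPM expression to log2(TPM+1)
#'
#' @param x an [expression_matrix()] with scale \code{"tpm"}.
#' @return an [expression_matrix()] on the \code{"log2tpm1"} scale.
#' @export
log_transform <- function(x) {
  assert_that(inherits(x, "expression_matrix"), "not an expression_matrix")
  assert_that(x$scale == "tpm",
              "log_transform expects TPM input; matrix is already log2(TPM+1)")
  assert_that(all(x$values >= 0), "negative TPM value")
  expression_matrix(log2(x$values + 1), scale = "log2tpm1")
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene IDs); within-set
#'   duplicates are removed.
#' @param descriptions optional character vector parallel to \code{sets}.
#' @return an object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  assert_that(is.list(sets), "sets must be a named list")
  assert_that(length(sets) == 0 || !is.null(names(sets)), "sets must be named")
  assert_that(!anyDuplicated(names(sets)), "duplicate set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  assert_that(all(lengths(sets) > 0), "empty gene set")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  structure(list(sets = sets, descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, median size %s\n", length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then gene IDs.
#' Duplicate genes within a line are dropped; a duplicated set name or a line
#' with fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()]; empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(stats::setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  assert_that(length(short) == 0,
              "GMT line ", if (length(short)) short[1] else "", " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1)
  assert_that(!anyDuplicated(nms), "duplicate set name in GMT: ",
              nms[duplicated(nms)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, vapply(fields, `[[`, "", 2))
}

#' Write a gene-set collection as GMT
#'
#' @param x a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a drug-response label table
#'
#' Long-format per-(sample, compound) AUC labels. Larger AUC means greater
#' resistance. At most one record per (sample, compound) pair.
#'
#' @param records data.frame with columns \code{sample_id}, \code{compound_id},
#'   \code{auc}; rows with missing AUC are dropped.
#' @return an object of class \code{drug_response_table} (a data.frame).
#' @export
drug_response_table <- function(records) {
  assert_that(all(c("sample_id", "compound_id", "auc") %in% colnames(records)),
              "records need columns sample_id, compound_id, auc")
  records <- data.frame(sample_id = as.character(records$sample_id),
                        compound_id = as.character(records$compound_id),
                        auc = as.numeric(records$auc),
                        stringsAsFactors = FALSE)
  records <- records[!is.na(records$auc), , drop = FALSE]
  assert_that(all(is.finite(records$auc)), "non-finite AUC value")
  key <- paste(records$sample_id, records$compound_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    sub <- records[key %in% dup, ]
    agg <- tapply(sub$auc, paste(sub$sample_id, sub$compound_id, sep = "\r"),
                  function(v) length(unique(v)))
    assert_that(all(agg == 1),
                "conflicting duplicate (sample, compound) AUC records")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  rownames(records) <- NULL
  class(records) <- c("drug_response_table", "data.frame")
  records
}

#' List compounds present in a drug-response table
#' @param labels a [drug_response_table()].
#' @return character vector of compound IDs.
#' @export
compounds <- function(labels) unique(labels$compound_id)

#' Read a drug-response CSV (sample_id, compound_id, auc)
#'
#' Blank or \code{NA} AUC cells are treated as missing and excluded.
#'
#' @param path CSV path with header \code{sample_id,compound_id,auc}.
#' @return a [drug_response_table()].
#' @export
read_drug_response <- function(path) {
  assert_that(file.exists(path), "label file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  assert_that(all(c("sample_id", "compound_id", "auc") %in% colnames(df)),
              "label CSV must have header sample_id,compound_id,auc")
  auc <- suppressWarnings(as.numeric(df$auc))
  missing <- is.na(df$auc) | trimws(df$auc) %in% c("", "NA")
  bad <- !missing & is.na(auc)
  assert_that(!any(bad), "non-numeric AUC at data row ", which(bad)[1])
  drug_response_table(data.frame(sample_id = df$sample_id,
                                 compound_id = df$compound_id,
                                 auc = auc)[!missing, , drop = FALSE])
}

#' Write a drug-response table as CSV
#' @param x a [drug_response_table()].
#' @param path output path.
#' @export
write_drug_response <- function(x, path) {
  out <- data.frame(sample_id = x$sample_id, compound_id = x$compound_id,
                    auc = num_chr(x$auc))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata CSV
#'
#' First column \code{sample_id}; remaining columns free-form (age, sex,
#' mutation flags, disease_label, ...). Empty cells become \code{NA}.
#'
#' @param path CSV path.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_sample_metadata <- function(path) {
  assert_that(file.exists(path), "metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  assert_that("sample_id" %in% colnames(df), "metadata CSV needs a sample_id column")
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample_id in metadata")
  df
}

#' Align expression samples with a compound's labels
#'
#' Returns exactly the samples present in both the expression matrix and the
#' compound's labelled records, in expression-matrix order, with the aligned
#' AUC label vector. Samples with missing labels are thereby excluded from
#' training.
#'
#' @param expr an [expression_matrix()] or any matrix-like object with sample
#'   columns (an enrichment matrix works too).
#' @param labels a [drug_response_table()].
#' @param compound compound ID to align on.
#' @return list with \code{sample_ids} (character) and \code{auc} (named
#'   numeric vector, same order).
#' @export
align_training_pairs <- function(expr, labels, compound) {
  assert_that(compound %in% labels$compound_id,
              "compound '", compound, "' has no labelled records")
  sids <- if (inherits(expr, "expression_matrix")) colnames(expr$values)
          else if (inherits(expr, "enrichment_matrix")) colnames(expr$scores)
          else colnames(expr)
  rec <- labels[labels$compound_id == compound, , drop = FALSE]
  keep <- sids[sids %in% rec$sample_id]
  assert_that(length(keep) > 0,
              "no overlap between expression samples and labelled samples for '",
              compound, "'")
  auc <- stats::setNames(rec$auc[match(keep, rec$sample_id)], keep)
  list(sample_ids = keep, auc = auc)
}
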