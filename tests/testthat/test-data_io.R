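test_that("GCT round trip preserves IDs, order and values", {
  x <- tiny_expr(5, 3)
  p <- withr::local_tempfile(fileext = ".gct")
  write_expression(x, p, "gct")
  y <- read_expression(p, "gct")
  expect_identical(rownames(y$values), rownames(x$values))
  expect_identical(colnames(y$values), colnames(x$values))
  expect_equal(y$values, x$values, tolerance = 1e-12)
  # TSV round trip too
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, p2, "tsv")
  expect_equal(read_expression(p2, "tsv")$values, x$values, tolerance = 1e-12)
})

test_that("duplicate gene rows collapse to the max-mean row with a warning", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "gA\t1\t1",
               "gB\t5\t7",
               "gA\t4\t6"), p)
  expect_warning(m <- read_expression(p, "tsv"), "collapsed")
  expect_equal(nrow(m$values), 2)
  expect_equal(unname(m$values["gA", ]), c(4, 6))  # mean 5 beats mean 1
})

test_that("malformed GCT files are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "2\t1", "Name\tDescription\ts1", "g1\tna\t1", "g2\tna\t2"), p)
  expect_error(read_expression(p, "gct"), "#1.2")
  writeLines(c("#1.2", "3\t1", "Name\tDescription\ts1", "g1\tna\t1", "g2\tna\t2"), p)
  expect_error(read_expression(p, "gct"), "declares")
  writeLines(c("#1.2", "2\t1", "Name\tDescription\ts1", "g1\tna\t1", "g2\tna\tabc"), p)
  expect_error(read_expression(p, "gct"), "non-numeric")
})

test_that("log_transform maps TPM elementwise and refuses log-scale input", {
  v <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- expression_matrix(v, "tpm")
  lt <- log_transform(m)
  expect_equal(unname(lt$values[1, 1]), 0)
  expect_equal(unname(lt$values[2, 1]), 1)
  expect_equal(unname(lt$values[1, 2]), 3)
  expect_identical(lt$scale, "log2tpm1")
  expect_error(log_transform(lt), "already")
  # random matrix against a naive loop
  set.seed(4)
  v <- matrix(stats::runif(30, 0, 50), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  lt <- log_transform(expression_matrix(v, "tpm"))
  for (i in 1:5) for (j in 1:6) {
    expect_equal(lt$values[i, j], log2(v[i, j] + 1))
  }
})

test_that("GMT reading dedups genes, keeps order, and rejects bad lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tB", "S2\td2\tC\tD", "S3\td3\tE"), p)
  gs <- read_gmt(p)
  expect_equal(length(gs), 3)
  expect_identical(names(gs$sets), c("S1", "S2", "S3"))
  expect_identical(gs$sets$S1, c("A", "B"))
  # round trip
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, p2)
  expect_identical(read_gmt(p2)$sets, gs$sets)
  # empty file -> empty collection
  writeLines(character(), p)
  expect_equal(length(read_gmt(p)), 0)
  # short line and duplicate names are errors
  writeLines("S1\tdesc_only", p)
  expect_error(read_gmt(p), "fewer than 3")
  writeLines(c("S1\td\tA", "S1\td\tB"), p)
  expect_error(read_gmt(p), "duplicate set name")
})

test_that("drug-response CSV: missing dropped, conflicts rejected, round trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,compound_id,auc",
               "s1,c1,7.25", "s2,c1,", "s3,c1,8.5", "s1,c2,NA", "s2,c2,6"), p)
  tab <- read_drug_response(p)
  expect_equal(nrow(tab), 3)
  expect_setequal(compounds(tab), c("c1", "c2"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_drug_response(tab, p2)
  tab2 <- read_drug_response(p2)
  expect_equal(tab2$auc, tab$auc, tolerance = 1e-12)
  expect_identical(tab2$sample_id, tab$sample_id)
  # conflicting duplicates
  writeLines(c("sample_id,compound_id,auc", "s1,c1,1", "s1,c1,2"), p)
  expect_error(read_drug_response(p), "conflicting")
  # agreeing duplicates are collapsed silently
  writeLines(c("sample_id,compound_id,auc", "s1,c1,1", "s1,c1,1"), p)
  expect_equal(nrow(read_drug_response(p)), 1)
})

test_that("align_training_pairs returns exactly the labelled intersection in expression order", {
  x <- tiny_expr(10, 5)
  lab <- drug_response_table(data.frame(
    sample_id = c("s02", "s04", "s05", "sX"), compound_id = "c1",
    auc = c(1, 2, 3, 4)))
  pr <- align_training_pairs(x, lab, "c1")
  expect_identical(pr$sample_ids, c("s02", "s04", "s05"))
  expect_equal(unname(pr$auc), c(1, 2, 3))
  expect_error(align_training_pairs(x, lab, "nope"), "no labelled records")
  disjoint <- drug_response_table(data.frame(
    sample_id = "zz", compound_id = "c1", auc = 1))
  expect_error(align_training_pairs(x, disjoint, "c1"), "no overlap")
})

test_that("alignment size matches the set-intersection oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    ns <- sample(4:30, 1)
    x <- tiny_expr(5, ns, seed = rep)
    labelled <- sample(sprintf("s%02d", sample.int(40, sample(2:25, 1))))
    lab <- drug_response_table(data.frame(sample_id = labelled,
                                          compound_id = "c", auc = seq_along(labelled)))
    expected <- length(intersect(colnames(x$values), labelled))
    if (expected == 0) {
      expect_error(align_training_pairs(x, lab, "c"), "no overlap")
    } else {
      expect_length(align_training_pairs(x, lab, "c")$sample_ids, expected)
    }
  }
})
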