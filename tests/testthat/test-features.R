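test_that("ssGSEA reproduces hand-enumerated N=4 scores", {
  e4 <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(ssgsea_score(e4, c("a", "b"), alpha = 0), 2.0)
  expect_equal(ssgsea_score(e4, c("c", "d"), alpha = 0), -2.0)
  expect_equal(ssgsea_score(e4, c("b", "c"), alpha = 0), 0)
})

test_that("ssGSEA engine equals the double-loop ECDF oracle on random instances", {
  set.seed(2024)
  for (rep in 1:60) {
    inst <- random_ssgsea_instance()
    expect_equal(ssgsea_score(inst$expr, inst$set, inst$alpha),
                 oracle_ssgsea(inst$expr, inst$set, inst$alpha),
                 tolerance = 1e-11)
  }
})

test_that("ssGSEA invariances: rank shift, sign symmetry, degenerate sets", {
  set.seed(5)
  expr <- stats::setNames(stats::runif(20, 0, 5), sprintf("g%02d", 1:20))
  s <- sample(names(expr), 6)
  # alpha = 0: adding a constant leaves ranks, hence ES, unchanged
  expect_equal(ssgsea_score(expr, s, 0), ssgsea_score(expr + 3.7, s, 0))
  # reversing the ranking negates ES when |S| = N - |S| (alpha = 0)
  half <- names(sort(expr, decreasing = TRUE))[1:10]
  expect_equal(ssgsea_score(-expr, half, 0), -ssgsea_score(expr, half, 0))
  # set covering all genes or missing entirely is an error
  expect_error(ssgsea_score(expr, names(expr), 0), "covers all")
  expect_error(ssgsea_score(expr, "absent", 0), "intersect")
})

test_that("ssgsea_matrix agrees per cell with ssgsea_score and drops out-of-bounds sets", {
  x <- tiny_expr(50, 5, seed = 7)
  sets <- gene_set_collection(list(
    A = sprintf("g%03d", 1:10), B = sprintf("g%03d", 21:28),
    tiny = sprintf("g%03d", 31:32),              # below min bound of 5
    alien = c("zz1", "zz2", "zz3", "zz4", "zz5") # no intersection
  ))
  expect_message(em <- ssgsea_matrix(x, sets, alpha = 0.75, bounds = c(5, 2000)),
                 "dropping 2/4")
  expect_identical(rownames(em$scores), c("A", "B"))
  for (sn in rownames(em$scores)) for (sm in colnames(em$scores)) {
    expect_equal(em$scores[sn, sm],
                 ssgsea_score(x$values[, sm], sets$sets[[sn]], 0.75),
                 tolerance = 1e-12)
  }
  # permuting samples permutes columns identically
  xp <- expression_matrix(x$values[, c(3, 1, 2, 5, 4)], "log2tpm1")
  emp <- suppressMessages(ssgsea_matrix(xp, sets))
  expect_equal(emp$scores, em$scores[, c(3, 1, 2, 5, 4)])
  # all sets dropped is an error
  expect_error(suppressMessages(ssgsea_matrix(x, gene_set_collection(
    list(onlytiny = c("g001", "g002"))))), "all gene sets dropped")
})

test_that("min-max scaler maps training to [0,1], clips queries, flags degenerates", {
  m <- rbind(f1 = c(2, 4, 6), f2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  sc <- fit_scaler(m)
  out <- apply_scaler(sc, m)
  expect_equal(unname(out["f1", ]), c(0, 0.5, 1))
  expect_true(sc$degenerate[["f2"]])
  expect_equal(unname(out["f2", ]), c(0, 0, 0))
  # query clipping below min and above max
  q <- rbind(f1 = c(-10, 100), f2 = c(0, 9))
  colnames(q) <- c("q1", "q2")
  oq <- apply_scaler(sc, q)
  expect_equal(unname(oq["f1", ]), c(0, 1))
  # idempotence: applying the fitted scaler to its own output is a no-op
  expect_equal(apply_scaler(sc, apply_scaler(sc, q)), apply_scaler(sc, q))
  # name mismatch errors list the symmetric difference
  bad <- rbind(f1 = c(1, 2), f3 = c(1, 2))
  colnames(bad) <- c("q1", "q2")
  expect_error(apply_scaler(sc, bad), "f2")
  expect_error(apply_scaler(sc, bad), "f3")
})

test_that("metadata augmentation encodes, scales, imputes and errors per contract", {
  feats <- matrix(stats::runif(6), 2, 3,
                  dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     age = c(30, 50, 70),
                     sex = c("F", "M", NA),
                     disease_label = "glioma")
  out <- augment_with_metadata(feats, meta, c("age", "sex"))
  expect_equal(unname(out["meta:age", ]), c(0, 0.5, 1))
  expect_equal(unname(colSums(out[c("meta:sex=F", "meta:sex=M"), ])),
               c(1, 1, 0))  # missing value -> all-zero indicators
  # encoder reuse applies training scaling to new samples, with clipping
  enc <- attr(out, "encoder")
  meta_q <- data.frame(sample_id = "q1", age = 90, sex = "F")
  featq <- matrix(0.5, 2, 1, dimnames = list(c("A", "B"), "q1"))
  outq <- augment_with_metadata(featq, meta_q, c("age", "sex"), encoder = enc)
  expect_equal(unname(outq["meta:age", 1]), 1)  # 90 clipped to training max
  expect_error(augment_with_metadata(feats, meta, c("age", "bmi")), "bmi")
})
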