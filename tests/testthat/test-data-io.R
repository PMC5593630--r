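test_that("TSV expression matrices round-trip and echo their contents", {
  paths <- generate_toy_fixtures()
  m <- read_expression_matrix(paths[["matrix"]])
  expect_s3_class(m, "ExpressionMatrix")
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(unclass(m)["gA", ]), c(1, 2, 3))
  expect_false(is_zscored(m))

  out <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, out)
  m2 <- read_expression_matrix(out)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-9)
})

test_that("GCT 1.2 headers are honoured and dimensions validated", {
  paths <- generate_toy_fixtures()
  g <- read_expression_matrix(paths[["gct"]], format = "gct")
  m <- read_expression_matrix(paths[["matrix"]])
  expect_equal(unclass(g), unclass(m))

  bad <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t3", readLines(paths[["gct"]])[-(1:2)]), bad)
  expect_error(read_expression_matrix(bad), "dimension mismatch")
  writeLines(c("not-a-gct", "3\t3"), bad)
  expect_error(read_expression_matrix(bad), "header")
})

test_that("duplicate gene rows collapse to their mean, order-independently", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t10", "B\t5\t6", "A\t3\t20"), tsv)
  expect_warning(m <- read_expression_matrix(tsv), "collapsed by mean")
  expect_equal(unname(unclass(m)["A", ]), c(2, 15))

  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t3\t20", "B\t5\t6", "A\t1\t10"), tsv2)
  m2 <- suppressWarnings(read_expression_matrix(tsv2))
  expect_equal(unclass(m2)[rownames(m), ], unclass(m)[rownames(m), ])
})

test_that("malformed matrices fail with the offending location", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\tx", "B\t2\t3"), tsv)
  expect_error(read_expression_matrix(tsv), "non-numeric")
  writeLines("gene\ts1", tsv)
  expect_error(read_expression_matrix(tsv), "empty")
})

test_that("GMT parsing, round trips, and edge cases behave", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines("BCELL\tna\tCD19\tMS4A1", gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(BCELL = c("CD19", "MS4A1")))

  big <- setNames(lapply(1:4, function(i) sprintf("s%d_g%03d", i, 1:100)),
                  paste0("SIG", 1:4))
  write_gmt(big, gmt)
  expect_identical(read_gmt(gmt), big)

  writeLines(character(), gmt)
  expect_equal(length(read_gmt(gmt)), 0L)

  writeLines("ONLY\ttwo", gmt)
  expect_error(read_gmt(gmt), "fewer than 3 fields")
})

test_that("annotations validate vocabularies and keep the category order", {
  paths <- generate_toy_fixtures()
  ann <- read_annotations(paths[["annotations"]])
  expect_s3_class(ann, "CohortAnnotation")
  expect_equal(ann$er_status[2], "ER-")
  # missing caai column is simply absent; a missing value becomes unknown
  df <- data.frame(sample_id = "s1", caai_status = NA)
  expect_equal(cohort_annotation(df)$caai_status, "unknown")

  expect_true(ann$infiltration_category[2] > ann$infiltration_category[1])
  expect_true(is.ordered(ann$infiltration_category))
  expect_equal(levels(ann$infiltration_category),
               c("absent", "mild", "moderate", "severe"))

  bad <- data.frame(sample_id = "s1", er_status = "positive")
  expect_error(cohort_annotation(bad), "positive")
})

test_that("z-scoring matches the hand formula and drops constant genes", {
  m <- expression_matrix(matrix(c(1, 2, 3,
                                  5, 5, 5,
                                  2, 4, 9), nrow = 3, byrow = TRUE,
                                dimnames = list(c("g1", "g2", "g3"),
                                                c("a", "b", "c"))))
  expect_warning(z <- zscore_transform(m), "constant")
  expect_equal(unname(unclass(z)["g1", ]), c(-1, 0, 1))  # mu=2, sd=1 (n-1)
  expect_false("g2" %in% rownames(z))
  expect_true(is_zscored(z))

  # definition: every surviving row has mean 0 and sd 1
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(unclass(z), 1, sd) - 1) < 1e-9))

  expect_error(zscore_transform(z), "already")
  one <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "s")))
  expect_error(zscore_transform(one), ">= 2 samples")
})

test_that("z-scoring an already-unit row is a distributional no-op", {
  set.seed(42)
  raw <- matrix(rnorm(50), 5, 10,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  z1 <- zscore_transform(expression_matrix(raw))
  z2 <- zscore_transform(expression_matrix(unclass(z1)))
  expect_equal(unclass(z2), unclass(z1), tolerance = 1e-9)
})

test_that("identifier invariants are enforced", {
  bad <- matrix(1:4, 2, 2, dimnames = list(c("g", "g"), c("a", "b")))
  expect_error(expression_matrix(bad), "duplicate gene")
  bad2 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("a", "a")))
  expect_error(expression_matrix(bad2), "duplicate sample")
})
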