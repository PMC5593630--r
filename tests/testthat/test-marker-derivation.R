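test_that("build_standards performs the tiered set algebra", {
  std <- build_standards(list(A = c("g1", "g2", "g3"), B = c("g3", "g4")))
  expect_setequal(std$A$high_positives, c("g1", "g2"))
  expect_setequal(std$A$low_positives, "g3")
  expect_setequal(std$A$negatives, "g4")
  expect_setequal(std$B$high_positives, "g4")
  expect_setequal(std$B$low_positives, "g3")
  expect_setequal(std$B$negatives, c("g1", "g2"))

  # identical lists leave no unique genes for either type
  expect_error(build_standards(list(A = c("g1", "g2"), B = c("g1", "g2"))),
               "zero unique genes")

  # 5-type table where only Th1/Th2 overlap: Bcell negatives are everyone
  # else's unique genes
  comp <- small_compendium()
  lists <- comp$seed_lists
  std5 <- build_standards(lists)
  shared <- intersect(lists$Th1, lists$Th2)
  expect_setequal(std5$Bcell$negatives,
                  setdiff(unlist(lists[c("CTL", "Th1", "Th2", "monocyte")]),
                          c(shared, lists$Bcell)))
})

test_that("standard tiers must be disjoint and non-empty", {
  expect_error(gene_standard("x", character(), "g1", "g2"), "high-tier")
  expect_error(gene_standard("x", "g1", "g1", "g2"), "overlap")
  expect_error(gene_standard("x", "g1", character(), character()),
               "negatives")
})

test_that("noiseless compendium ranks every program gene above non-program genes", {
  comp <- small_compendium(noise_sd = 0)
  # constant (all-zero) background genes are dropped by the z-transform
  z <- suppressWarnings(zscore_transform(comp$expression))
  ms <- suppressWarnings(nanodissect(z, comp$standards$Bcell,
                                     derivation_params(seed = 3)))
  ranked <- ms$ranked
  prog <- comp$programs$Bcell
  worst_prog <- max(match(prog, ranked$gene))
  best_other <- min(match(setdiff(ranked$gene, prog), ranked$gene))
  expect_lt(worst_prog, best_other)
})

test_that("single supervised fit matches the centroid-correlation oracle", {
  # 20-gene toy, no low tier: one iteration, ranking should agree with
  # correlation to the positive-class centroid in its top 5
  set.seed(11)
  n_s <- 40
  x <- matrix(rnorm(20 * n_s), nrow = 20,
              dimnames = list(sprintf("t%02d", 1:20), sprintf("s%02d", 1:n_s)))
  on <- rep(c(TRUE, FALSE), each = n_s / 2)
  x[1:5, on] <- x[1:5, on] + 2.5    # the positive standard's own pattern
  x[16:20, !on] <- x[16:20, !on] + 2.5
  z <- zscore_transform(expression_matrix(x))
  std <- gene_standard("toy", high_positives = sprintf("t%02d", 1:5),
                       negatives = sprintf("t%02d", 16:20))
  ms <- nanodissect(z, std, derivation_params(seed = 1))

  centroid <- colMeans(unclass(z)[std$high_positives, ])
  oracle <- sort(apply(unclass(z), 1, cor, y = centroid), decreasing = TRUE)
  expect_setequal(ms$ranked$gene[1:5], names(oracle)[1:5])
  expect_equal(ms$iterations, 1L)
})

test_that("promotion grows monotonically and the default signature has 100 genes", {
  d <- default_derivation()
  ms <- d$markers$Th1
  expect_equal(ms$n_selected, 100L)
  expect_length(ms$signature, 100L)
  # ranked scores are non-increasing and the signature is the ranked head
  expect_true(all(diff(ms$ranked$score) <= 1e-12))
  expect_identical(ms$signature, ms$ranked$gene[1:100])
})

test_that("ranking is invariant to sample-column permutation", {
  comp <- small_compendium(seed = 21)
  z <- suppressWarnings(zscore_transform(comp$expression))
  perm <- sample(ncol(z))
  z_perm <- expression_matrix(unclass(z)[, perm], zscored = TRUE)
  p <- derivation_params(seed = 4)
  r1 <- suppressWarnings(nanodissect(z, comp$standards$CTL, p))
  r2 <- suppressWarnings(nanodissect(z_perm, comp$standards$CTL, p))
  expect_identical(r1$ranked$gene, r2$ranked$gene)
  expect_equal(r1$ranked$score, r2$ranked$score, tolerance = 1e-8)
})

test_that("select_top_markers applies the lexicographic boundary tie-break", {
  sc <- c(a = 5, c = 4, b = 4, d = 1)
  ms <- immunodissect:::marker_set("toy", sc, top_n = 3L)
  expect_identical(select_top_markers(ms, 3L)$signature, c("a", "b", "c"))
  expect_identical(select_top_markers(ms, 2L)$signature, c("a", "b"))
  expect_identical(select_top_markers(ms, 4L)$signature, c("a", "b", "c", "d"))
  expect_error(select_top_markers(ms, 0L), "positive")
  expect_error(select_top_markers(ms, 5L), "exceeds")
})

test_that("cross-validation AUC is exact on separable toys and matches the U statistic", {
  # AUROC equals the Mann-Whitney U / (n_pos * n_neg), by enumeration
  pos <- c(0.9, 0.8, 0.4, 0.35)
  neg <- c(0.7, 0.3, 0.2, 0.1)
  u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(immunodissect:::auroc(pos, neg), u / 16, tolerance = 1e-12)

  comp <- small_compendium(noise_sd = 0)
  z <- suppressWarnings(zscore_transform(comp$expression))
  cv <- suppressWarnings(crossval_auc(z, comp$standards$Bcell,
                                      derivation_params(seed = 2)))
  expect_equal(cv$mean_auc, 1.0, tolerance = 1e-12)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  comp <- small_compendium(seed = 13)
  z <- suppressWarnings(zscore_transform(comp$expression))
  std <- comp$standards$CTL
  genes <- c(std$high_positives, std$negatives)
  aucs <- vapply(1:20, function(r) {
    perm <- withr::with_seed(1000 + r, sample(genes))
    k <- length(std$high_positives)
    null_std <- gene_standard("null", perm[1:k], character(),
                              perm[(k + 1):length(perm)])
    suppressWarnings(
      crossval_auc(z, null_std, derivation_params(seed = r))$mean_auc)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("degenerate and undersized standards are rejected", {
  z <- toy_zmatrix()
  std <- gene_standard("x", c("gA", "gB", "gC", "gD", "gE"),
                       negatives = "gF")
  expect_error(suppressWarnings(nanodissect(z, std, derivation_params())),
               "fewer than 5|no negatives")
  flat <- expression_matrix(
    matrix(rep(c(1, 2, 1, 2), 6), nrow = 6, byrow = TRUE,
           dimnames = list(paste0("g", 1:6), paste0("s", 1:4))),
    zscored = FALSE)
  std2 <- gene_standard("x", paste0("g", 1:5), negatives = "g6")
  expect_error(suppressWarnings(nanodissect(flat, std2, derivation_params())),
               "identical")
})
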