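# Iterative semi-supervised marker derivation ("nanodissection"-style).
#
# Genes are instances, a gene's feature vector is its z-scored expression
# profile across the compendium samples. A ridge-regularized linear model is
# fit on high-tier positives vs negatives, every gene is scored by its signed
# distance to the decision boundary, low-tier positives scoring above a
# quantile of the low tier are promoted into the training positives, and the
# fit is repeated until the promoted set stabilises. The final score ranks
# all genes; the signature is the top-N.

#' Derivation parameters
#'
#' @param regularization ridge penalty (glmnet lambda, alpha = 0) for the
#'   linear discriminant; the contract is the ranked score, not coefficients.
#' @param max_iterations promotion rounds before giving up (warn) (default 10).
#' @param promotion_threshold quantile of the low tier's decision scores above
#'   which low-tier positives are promoted each round, in (0,1); default 0.5.
#' @param cv_folds folds for [crossval_auc()] (default 5).
#' @param top_n signature size (default 100, the published cutoff).
#' @param seed integer seed for fold assignment.
#' @return a `DerivationParams` list.
#' @export
derivation_params <- function(regularization = 0.1, max_iterations = 10L,
                              promotion_threshold = 0.5, cv_folds = 5L,
                              top_n = 100L, seed = 1L) {
  stopifnot(regularization > 0, max_iterations >= 1L,
            promotion_threshold > 0, promotion_threshold < 1,
            cv_folds >= 2L, top_n >= 1L)
  structure(list(regularization = regularization,
                 max_iterations = as.integer(max_iterations),
                 promotion_threshold = promotion_threshold,
                 cv_folds = as.integer(cv_folds),
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "DerivationParams")
}

# Ridge linear discriminant on +/-1 labels; returns a score for every row of
# `features`. Solved in closed form, (X'X + lambda I) w = X'y on centered
# training data, so the fit is exact, deterministic, and invariant to sample
# (feature) permutation up to float rounding; the separable-limit ranking is
# preserved.
ridge_scores <- function(features, pos_idx, neg_idx, lambda) {
  x <- features[c(pos_idx, neg_idx), , drop = FALSE]
  if (nrow(unique(x)) < 2L)
    stop2("degenerate training set: all feature rows identical")
  y <- c(rep(1, length(pos_idx)), rep(-1, length(neg_idx)))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  w <- solve(crossprod(xc) + diag(lambda, ncol(xc)),
             crossprod(xc, y - mean(y)))
  drop(sweep(features, 2L, mu) %*% w) + mean(y)
}

#' Derive a ranked marker set for one cell type
#'
#' Runs the iterative train/score/promote loop against a z-scored compendium
#' and returns every compendium gene ranked by its final decision score,
#' with the top `params$top_n` selected as the signature. Genes used as
#' training positives remain eligible for the ranking but are flagged.
#'
#' @param compendium an `ExpressionMatrix`; z-scored per gene (a raw matrix
#'   is z-scored internally).
#' @param standard a `GeneStandard`; standard genes absent from the
#'   compendium are dropped with a warning, and fewer than 5 surviving
#'   high-tier positives is an error.
#' @param params a [derivation_params()] list.
#' @return a `MarkerSet`: `ranked` (data.frame gene/score/in_training sorted
#'   by non-increasing score), `signature`, `n_selected`, plus the number of
#'   promotion iterations run.
#' @export
nanodissect <- function(compendium, standard, params = derivation_params()) {
  stopifnot(inherits(standard, "GeneStandard"))
  compendium <- as_expression_matrix(compendium)
  if (!is_zscored(compendium)) compendium <- zscore_transform(compendium)
  feats <- unclass(compendium)  # instances = genes (rows), features = samples

  keep_present <- function(genes, tier) {
    present <- intersect(genes, rownames(feats))
    if (length(present) < length(genes))
      warning(length(genes) - length(present), " ", tier,
              " standard gene(s) absent from compendium, dropped")
    present
  }
  high <- keep_present(standard$high_positives, "high-positive")
  low <- keep_present(standard$low_positives, "low-positive")
  neg <- keep_present(standard$negatives, "negative")
  if (length(high) < 5L)
    stop2("fewer than 5 high-tier positives present in compendium for ",
          standard$cell_type)
  if (!length(neg)) stop2("no negatives present in compendium")

  pos <- high
  promoted <- character()
  iter <- 0L
  converged <- length(low) == 0L
  scores <- NULL
  repeat {
    iter <- iter + 1L
    scores <- ridge_scores(feats, match(pos, rownames(feats)),
                           match(neg, rownames(feats)),
                           params$regularization)
    names(scores) <- rownames(feats)
    if (length(low)) {
      thr <- stats::quantile(scores[low], params$promotion_threshold,
                             type = 7, names = FALSE)
      newly <- union(promoted, low[scores[low] >= thr])
      if (setequal(newly, promoted)) { converged <- TRUE; break }
      promoted <- newly
      pos <- union(high, promoted)
    } else break
    if (iter >= params$max_iterations) break
  }
  if (!converged && length(low)) {
    if (iter >= params$max_iterations)
      warning("promotion did not converge in ", params$max_iterations,
              " iterations; returning last iterate")
    # score with the final positive set
    scores <- ridge_scores(feats, match(pos, rownames(feats)),
                           match(neg, rownames(feats)),
                           params$regularization)
    names(scores) <- rownames(feats)
  }

  marker_set(standard$cell_type, scores, training = union(pos, neg),
             top_n = min(params$top_n, length(scores)), iterations = iter)
}

# Construct a MarkerSet from a named score vector. Ties broken by gene symbol
# so the ranking and the top-N cut are deterministic.
marker_set <- function(cell_type, scores, training = character(),
                       top_n, iterations = NA_integer_) {
  ord <- order(-scores, names(scores), method = "radix")
  ranked <- data.frame(gene = names(scores)[ord],
                       score = unname(scores)[ord],
                       in_training = names(scores)[ord] %in% training,
                       stringsAsFactors = FALSE)
  structure(list(cell_type = cell_type, ranked = ranked,
                 signature = ranked$gene[seq_len(top_n)],
                 n_selected = as.integer(top_n),
                 iterations = iterations),
            class = "MarkerSet")
}

#' @export
print.MarkerSet <- function(x, ...) {
  cat(sprintf("MarkerSet '%s': %d ranked genes, signature of %d\n",
              x$cell_type, nrow(x$ranked), x$n_selected))
  print(utils::head(x$ranked, 5L))
  invisible(x)
}

#' Shrink a marker set to its top-n signature
#'
#' Boundary ties are already resolved lexicographically by gene symbol in the
#' stored ranking, so the selection is deterministic.
#'
#' @param ranked a `MarkerSet`.
#' @param n signature size, 1 <= n <= number of ranked genes.
#' @return the `MarkerSet` with `signature`/`n_selected` updated.
#' @export
select_top_markers <- function(ranked, n) {
  stopifnot(inherits(ranked, "MarkerSet"))
  if (n <= 0L) stop2("n must be positive")
  if (n > nrow(ranked$ranked))
    stop2("n exceeds the number of ranked genes")
  ranked$signature <- ranked$ranked$gene[seq_len(n)]
  ranked$n_selected <- as.integer(n)
  ranked
}

# Area under the ROC curve via the rank (Mann-Whitney) identity.
auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos); nn <- length(scores_neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated AUROC of the derivation classifier
#'
#' Stratified k-fold assignment over the standard genes (high and low
#' positives vs negatives, each tier split separately so every fold holds out
#' both tiers). The full iterative procedure runs inside each training fold
#' only; held-out standard genes are scored by the resulting discriminant and
#' AUROC is computed over them (positives = both tiers).
#'
#' @inheritParams nanodissect
#' @return list with `fold_auc` (numeric, length `cv_folds`) and `mean_auc`.
#' @export
crossval_auc <- function(compendium, standard, params = derivation_params()) {
  stopifnot(inherits(standard, "GeneStandard"))
  compendium <- as_expression_matrix(compendium)
  if (!is_zscored(compendium)) compendium <- zscore_transform(compendium)
  k <- params$cv_folds
  pos_all <- intersect(c(standard$high_positives, standard$low_positives),
                       rownames(compendium))
  neg_all <- intersect(standard$negatives, rownames(compendium))
  if (length(pos_all) < k || length(neg_all) < k)
    stop2("need at least cv_folds genes in each class")

  fold_of <- function(genes) {
    f <- rep_len(seq_len(k), length(genes))
    stats::setNames(sample(f), genes)
  }
  folds <- with_seed(params$seed, {
    c(fold_of(intersect(standard$high_positives, rownames(compendium))),
      fold_of(intersect(standard$low_positives, rownames(compendium))),
      fold_of(neg_all))
  })

  fold_auc <- vapply(seq_len(k), function(f) {
    held <- names(folds)[folds == f]
    train_std <- gene_standard(
      standard$cell_type,
      setdiff(intersect(standard$high_positives, rownames(compendium)), held),
      setdiff(intersect(standard$low_positives, rownames(compendium)), held),
      setdiff(neg_all, held))
    test_pos <- intersect(held, pos_all)
    test_neg <- intersect(held, neg_all)
    if (!length(test_pos) || !length(test_neg))
      stop2("fold ", f, " holds out only one class; use fewer folds")
    ms <- suppressWarnings(nanodissect(compendium, train_std, params))
    sc <- stats::setNames(ms$ranked$score, ms$ranked$gene)
    auroc(sc[test_pos], sc[test_neg])
  }, numeric(1L))

  list(fold_auc = fold_auc, mean_auc = mean(fold_auc))
}
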