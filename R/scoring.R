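# Per-sample signature scores: the mean of z-score transformed expression
# over a signature's genes (d_s = (1/n) sum_i z_is), with marker genes not
# assayed in the matrix excluded from the average.

#' Score samples against one gene signature
#'
#' @param z a z-scored `ExpressionMatrix`.
#' @param signature character vector of gene symbols.
#' @param name signature label used in messages.
#' @return named numeric vector of per-sample scores with attribute
#'   `n_genes_used` (signature genes found in the matrix).
#' @export
signature_score <- function(z, signature, name = "signature") {
  z <- as_expression_matrix(z, zscored = isTRUE(attr(z, "zscored")))
  if (!is_zscored(z))
    stop2("matrix must be z-scored before scoring (see zscore_transform)")
  genes <- match_genes(unique(signature), z)
  if (!length(genes))
    stop2("no genes of signature '", name, "' are present in the matrix")
  if (length(genes) < length(unique(signature)))
    message(length(unique(signature)) - length(genes), " gene(s) of '", name,
            "' not assayed; excluded from averaging")
  sc <- colMeans(unclass(z)[genes, , drop = FALSE])
  if (any(!is.finite(sc))) stop2("non-finite score computed for '", name, "'")
  attr(sc, "n_genes_used") <- length(genes)
  sc
}

#' Total lymphocyte score
#'
#' Combines the genes of all supplied lymphocyte signatures into one
#' deduplicated union before averaging, rather than averaging the per-type
#' scores, so each gene contributes exactly once.
#'
#' @param z a z-scored `ExpressionMatrix`.
#' @param signatures list of gene vectors (typically B cell, CTL, Th1, Th2).
#' @return scores as in [signature_score()].
#' @export
total_lymphocyte_score <- function(z, signatures) {
  stopifnot(is.list(signatures), length(signatures) >= 1L)
  signature_score(z, unique(unlist(signatures, use.names = FALSE)),
                  name = "total_lymphocyte")
}

#' Estrogen-receptor activity score and call
#'
#' The same averaging score applied to an ER-associated gene set. A score
#' below zero corresponds to an ER- sample and above zero to ER+; a score of
#' exactly zero is left uncalled.
#'
#' @param z a z-scored `ExpressionMatrix`.
#' @param er_signature ER-associated gene set (e.g. the van 't Veer ER genes
#'   for real cohorts, or the planted ER program for synthetic ones).
#' @return scores as in [signature_score()].
#' @export
er_activity_score <- function(z, er_signature) {
  signature_score(z, er_signature, name = "er_activity")
}

#' @rdname er_activity_score
#' @param score numeric vector of ER activity scores.
#' @return `er_call()`: character vector in `{"ER+", "ER-", "unknown"}`.
#' @export
er_call <- function(score) {
  out <- ifelse(score > 0, "ER+", ifelse(score < 0, "ER-", "unknown"))
  if (any(score == 0))
    message(sum(score == 0), " sample(s) with ER score exactly 0 left uncalled")
  out
}

#' Build a score table for a cohort
#'
#' One column per signature plus `total` (union of the lymphocyte
#' signatures) and, when an ER set is given, `er_activity`.
#'
#' @param z a z-scored `ExpressionMatrix`.
#' @param signatures named list of signature gene vectors.
#' @param er_signature optional ER gene set.
#' @return data.frame (`ScoreTable`) with `sample_id`, one numeric column per
#'   score, and attribute `n_genes_used` (named integer vector).
#' @export
score_table <- function(z, signatures, er_signature = NULL) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  cols <- lapply(names(signatures), function(nm)
    signature_score(z, signatures[[nm]], name = nm))
  names(cols) <- names(signatures)
  cols$total <- total_lymphocyte_score(z, signatures)
  if (!is.null(er_signature))
    cols$er_activity <- er_activity_score(z, er_signature)
  out <- data.frame(sample_id = colnames(z), lapply(cols, as.numeric),
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <-
    vapply(cols, function(x) attr(x, "n_genes_used"), integer(1L))
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Robustness of a signature's ordinal trend to gene dropout
#'
#' Emulates marker genes missing from a platform: for each removal fraction f
#' and repetition, `round(f * n)` signature genes (at least 1 for f > 0) are
#' removed without replacement, the score is recomputed, and the Kendall
#' tau-b correlation (with tie-corrected p-value) between the recomputed
#' score and the ordered infiltration categories is recorded.
#'
#' @param z a z-scored `ExpressionMatrix`.
#' @param signature gene vector.
#' @param categories ordered factor (or character coercible to the
#'   absent/mild/moderate/severe order) aligned with the matrix samples.
#' @param fractions removal-fraction grid in `[0, 1)`; default 0 to 0.95 in
#'   0.05 steps. Alternatively pass `remove_counts` to remove fixed numbers
#'   of genes per step (e.g. 50 genes, 50 times); counts are converted to
#'   fractions of the assayed signature.
#' @param remove_counts optional integer grid of absolute removal counts,
#'   overriding `fractions`.
#' @param reps repetitions per fraction (default 50).
#' @param seed RNG seed.
#' @param alpha significance level used for `max_preserved_fraction`.
#' @return a `RobustnessResult`: data.frame `results` (fraction, rep, tau,
#'   p_value, n_genes_used) plus `max_preserved_fraction`, the largest grid
#'   fraction at which all repetitions are significant (NA if none).
#' @export
robustness_analysis <- function(z, signature, categories,
                                fractions = seq(0, 0.95, by = 0.05),
                                remove_counts = NULL,
                                reps = 50L, seed = 1L, alpha = 0.05) {
  if (!is.null(remove_counts)) {
    n_sig <- length(match_genes(unique(signature), z))
    fractions <- as.integer(remove_counts) / n_sig
  }
  if (any(fractions >= 1)) stop2("removal fractions must be < 1")
  if (any(fractions < 0)) stop2("removal fractions must be >= 0")
  stopifnot(reps >= 1L)
  if (!is.ordered(categories))
    categories <- factor(as.character(categories),
                         levels = INFILTRATION_LEVELS, ordered = TRUE)
  keep <- !is.na(categories)
  if (nlevels(droplevels(categories[keep])) < 2L)
    stop2("need >= 2 represented category levels")
  genes <- match_genes(unique(signature), z)
  if (length(genes) < 2L) stop2("signature too small for dropout analysis")
  zk <- z[, keep, drop = FALSE]
  cat_rank <- as.integer(categories[keep])

  tau_test <- function(gs) {
    sc <- colMeans(unclass(zk)[gs, , drop = FALSE])
    ct <- suppressWarnings(stats::cor.test(sc, cat_rank, method = "kendall",
                                           exact = FALSE))
    c(tau = unname(ct$estimate), p = ct$p.value)
  }

  res <- with_seed(seed, {
    do.call(rbind, lapply(fractions, function(f) {
      n_rm <- if (f == 0) 0L else max(1L, round(f * length(genes)))
      if (n_rm >= length(genes)) stop2("fraction ", f, " removes every gene")
      do.call(rbind, lapply(seq_len(reps), function(r) {
        gs <- if (n_rm == 0L) genes else
          genes[-sample.int(length(genes), n_rm)]
        tt <- tau_test(gs)
        data.frame(fraction = f, rep = r, tau = tt[["tau"]],
                   p_value = tt[["p"]], n_genes_used = length(gs))
      }))
    }))
  })

  ok <- vapply(fractions, function(f)
    all(res$p_value[res$fraction == f] < alpha), logical(1L))
  mpf <- if (any(ok)) max(fractions[ok]) else NA_real_
  structure(list(results = res, fractions = fractions, reps = as.integer(reps),
                 seed = as.integer(seed), alpha = alpha,
                 max_preserved_fraction = mpf),
            class = "RobustnessResult")
}

#' @export
print.RobustnessResult <- function(x, ...) {
  cat(sprintf(
    "RobustnessResult: %d fractions x %d reps; trend preserved up to %s\n",
    length(x$fractions), x$reps,
    if (is.na(x$max_preserved_fraction)) "no fraction"
    else sprintf("%.0f%% removal", 100 * x$max_preserved_fraction)))
  invisible(x)
}
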