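#' Expression matrix constructor
#'
#' Wraps a genes x samples numeric matrix with validated, unique gene and
#' sample identifiers and a flag recording whether rows have been z-score
#' transformed. All downstream coordinates are identifier-based, never
#' positional, so column order is irrelevant.
#'
#' @param values numeric matrix, genes as rows, with rownames (gene symbols)
#'   and colnames (sample identifiers).
#' @param zscored logical; `TRUE` if rows are already z-score transformed.
#' @return an `ExpressionMatrix` (a classed numeric matrix with a `zscored`
#'   attribute).
#' @export
expression_matrix <- function(values, zscored = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop2("expression matrix is empty")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop2("expression matrix needs row (gene) and column (sample) names")
  gid <- trimws(gid)
  sid <- trimws(sid)
  if (anyDuplicated(gid))
    stop2("duplicate gene identifiers: ",
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop2("duplicate sample identifiers: ",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  rownames(values) <- gid
  colnames(values) <- sid
  structure(values, zscored = isTRUE(zscored),
            class = c("ExpressionMatrix", class(matrix())))
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, zscored = attr(x, "zscored"),
                     class = class(x))
  out
}

#' Test or read the z-scored flag
#' @param m an `ExpressionMatrix`.
#' @return logical flag.
#' @export
is_zscored <- function(m) isTRUE(attr(m, "zscored"))

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_zscored(x)) "z-scored" else "raw"))
  if (nrow(x) > 0) {
    k <- min(5L, nrow(x)); l <- min(5L, ncol(x))
    print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE], ...)
    if (nrow(x) > k || ncol(x) > l) cat("...\n")
  }
  invisible(x)
}

#' Per-gene z-score transformation
#'
#' For each gene g and sample s computes z_gs = (x_gs - mu_g) / sigma_g where
#' mu_g and sigma_g are the mean and (sample, n-1 denominator) standard
#' deviation of the gene across all samples in the cohort. Genes with zero
#' dispersion carry no signal and are dropped with a warning rather than set
#' to zero, which would fabricate signal in downstream averaged scores.
#'
#' @param m an `ExpressionMatrix`, not yet z-scored, with at least 2 samples.
#' @return a z-scored `ExpressionMatrix`; constant genes removed.
#' @export
zscore_transform <- function(m) {
  m <- as_expression_matrix(m)
  if (is_zscored(m)) stop2("matrix is already z-scored")
  if (ncol(m) < 2L)
    stop2("z-score transform needs >= 2 samples (sigma undefined for 1)")
  mu <- rowMeans(m)
  sd_g <- apply(unclass(m), 1L, stats::sd)
  keep <- sd_g > 0 & is.finite(sd_g)
  if (!all(keep))
    warning(sum(!keep), " constant gene(s) dropped during z-scoring: ",
            paste(utils::head(rownames(m)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  if (!any(keep)) stop2("all genes constant; nothing to z-score")
  z <- (unclass(m)[keep, , drop = FALSE] - mu[keep]) / sd_g[keep]
  expression_matrix(z, zscored = TRUE)
}

# Coerce plain matrices, validating identifiers.
as_expression_matrix <- function(m, zscored = FALSE) {
  if (inherits(m, "ExpressionMatrix")) return(m)
  expression_matrix(as.matrix(m), zscored = zscored)
}

# Identifier-based gene lookup with a case-insensitive rescue pass (logged).
match_genes <- function(genes, m) {
  genes <- trimws(genes)
  hit <- genes[genes %in% rownames(m)]
  miss <- setdiff(genes, hit)
  if (length(miss)) {
    idx <- match(toupper(miss), toupper(rownames(m)))
    rescued <- rownames(m)[idx[!is.na(idx)]]
    if (length(rescued)) {
      message(length(rescued),
              " gene(s) matched case-insensitively: ",
              paste(utils::head(rescued, 5L), collapse = ", "))
      hit <- c(hit, rescued)
    }
  }
  unique(hit)
}
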