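#' Tiered gene standard for one cell type
#'
#' High-tier positives are genes unique to the cell type, low-tier positives
#' are genes it shares with other cell types, negatives are the unique genes
#' of the other cell types. The three tiers must be pairwise disjoint and the
#' high tier and negatives non-empty.
#'
#' @param cell_type label.
#' @param high_positives,low_positives,negatives character vectors of gene
#'   symbols.
#' @return a `GeneStandard`.
#' @export
gene_standard <- function(cell_type, high_positives, low_positives = character(),
                          negatives) {
  high_positives <- unique(trimws(high_positives))
  low_positives <- unique(trimws(low_positives))
  negatives <- unique(trimws(negatives))
  if (!length(high_positives))
    stop2("no high-tier positives for cell type '", cell_type, "'")
  if (!length(negatives))
    stop2("no negatives for cell type '", cell_type, "'")
  pools <- list(high = high_positives, low = low_positives, neg = negatives)
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(pools[[i]], pools[[j]])
    if (length(ov))
      stop2(sprintf("standard tiers '%s' and '%s' overlap for %s: %s",
                    names(pools)[i], names(pools)[j], cell_type,
                    paste(utils::head(ov, 5L), collapse = ", ")))
  }
  structure(list(cell_type = cell_type, high_positives = high_positives,
                 low_positives = low_positives, negatives = negatives),
            class = "GeneStandard")
}

#' @export
print.GeneStandard <- function(x, ...) {
  cat(sprintf("GeneStandard '%s': %d high positives, %d low positives, %d negatives\n",
              x$cell_type, length(x$high_positives), length(x$low_positives),
              length(x$negatives)))
  invisible(x)
}

#' Build tiered standards from per-cell-type gene lists
#'
#' For each cell type, genes appearing in no other list become high-tier
#' positives, genes shared with at least one other cell type become low-tier
#' positives, and the union of the other cell types' unique genes become
#' negatives.
#'
#' @param cell_type_genes named list (>= 2 cell types) of non-empty gene
#'   vectors.
#' @return named list of `GeneStandard`, one per cell type.
#' @export
build_standards <- function(cell_type_genes) {
  stopifnot(is.list(cell_type_genes))
  if (length(cell_type_genes) < 2L) stop2("need >= 2 cell types")
  if (is.null(names(cell_type_genes)) || any(!nzchar(names(cell_type_genes))))
    stop2("cell type lists must be named")
  cell_type_genes <- lapply(cell_type_genes, function(g) unique(trimws(g)))
  if (any(lengths(cell_type_genes) == 0L)) stop2("empty gene list supplied")

  types <- names(cell_type_genes)
  uniques <- lapply(types, function(ct) {
    others <- unlist(cell_type_genes[setdiff(types, ct)], use.names = FALSE)
    setdiff(cell_type_genes[[ct]], others)
  })
  names(uniques) <- types

  out <- lapply(types, function(ct) {
    high <- uniques[[ct]]
    if (!length(high))
      stop2("cell type '", ct, "' has zero unique genes; no high-tier positives")
    low <- setdiff(cell_type_genes[[ct]], high)
    neg <- unique(unlist(uniques[setdiff(types, ct)], use.names = FALSE))
    gene_standard(ct, high, low, neg)
  })
  names(out) <- types
  out
}
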