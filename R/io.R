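# Readers and writers for the plain-text formats the pipeline consumes:
# expression as TSV (gene column + sample columns) or GCT 1.2, gene sets as
# GMT, per-sample clinical annotations as TSV.

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: first column gene symbols, remaining columns one per sample,
#' header row with sample identifiers. GCT 1.2: "#1.2" line, a dimensions
#' line, then the TSV body with Name/Description columns; declared dimensions
#' are validated against the body. Duplicate gene rows are collapsed by their
#' mean with a warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @return an `ExpressionMatrix` (raw, not z-scored).
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"

  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !startsWith(hdr[[1L]], "#1.2"))
      stop2("malformed GCT header at line 1 of ", path, " (expected '#1.2')")
    dims <- suppressWarnings(as.integer(strsplit(hdr[[2L]], "\t")[[1L]][1:2]))
    if (any(is.na(dims)))
      stop2("malformed GCT dimensions at line 2 of ", path)
    df <- utils::read.delim(path, skip = 2L, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop2("GCT body needs Name, Description and >=1 sample")
    genes <- as.character(df[[1L]])
    body <- df[, -(1:2), drop = FALSE]
    if (nrow(df) != dims[1L] || ncol(body) != dims[2L])
      stop2(sprintf(
        "GCT dimension mismatch in %s: declared %d x %d, body %d x %d",
        path, dims[1L], dims[2L], nrow(df), ncol(body)))
    first_data_line <- 4L
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
      stop2("empty or column-less expression matrix: ", path)
    genes <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    first_data_line <- 2L
  }

  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop2(sprintf("non-numeric value %s at line %d, column '%s' of %s",
                    deparse(v[bad]), bad + first_data_line - 1L,
                    colnames(body)[j], path))
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- trimws(genes)

  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning(length(dup), " duplicate gene row(s) collapsed by mean: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE) /
      as.vector(table(rownames(mat))[unique(rownames(mat))])
  }
  expression_matrix(mat)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 10 significant digits so read/write round trips
#' are lossless at that precision.
#'
#' @param m an `ExpressionMatrix` or plain named matrix.
#' @param path output path.
#' @param gene_col name for the gene column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, gene_col = "gene") {
  m <- as_expression_matrix(m, zscored = isTRUE(attr(m, "zscored")))
  body <- apply(unclass(m), 2L, function(col) formatC(col, digits = 10,
                                                      format = "g"))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  df <- data.frame(rownames(m), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name TAB description TAB gene TAB gene ... An empty file
#' yields an empty list.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop2(sprintf("malformed GMT line %d in %s: fewer than 3 fields", i, path))
    sets[[f[[1L]]]] <- trimws(f[-(1:2)])
  }
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled); default "na".
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop2("gene sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Controlled vocabularies for the clinical annotation columns.
ANNOTATION_VOCAB <- list(
  er_status = c("ER+", "ER-", "unknown"),
  subtype = c("basal", "HER2", "luminal A", "luminal B", "normal-like",
              "unknown"),
  infiltration_category = c("absent", "mild", "moderate", "severe",
                            "unknown"),
  caai_status = c("positive", "negative", "unknown"),
  timepoint = c("pre", "day90", "none")
)

INFILTRATION_LEVELS <- c("absent", "mild", "moderate", "severe")

#' Validate a cohort annotation table
#'
#' Checks categorical columns against their controlled vocabularies, fills
#' missing values with "unknown", and stores the infiltration category as an
#' ordered factor (absent < mild < moderate < severe). Unknown extra columns
#' are preserved untouched.
#'
#' @param df data.frame with at least a `sample_id` column; recognised
#'   columns: `patient_id`, `er_status`, `subtype`, `infiltration_category`,
#'   `caai_status`, `survival_time`, `event`, `timepoint`, and any
#'   `true_fraction_*` ground-truth columns.
#' @return validated data.frame of class `CohortAnnotation`.
#' @export
cohort_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) stop2("annotation table needs 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample_id in annotations")
  for (col in names(ANNOTATION_VOCAB)) {
    if (!col %in% names(df)) next
    v <- as.character(df[[col]])
    v[is.na(v) | !nzchar(trimws(v))] <-
      if (col == "timepoint") "none" else "unknown"
    bad <- setdiff(unique(v), ANNOTATION_VOCAB[[col]])
    if (length(bad))
      stop2(sprintf("unrecognized %s value(s): %s (allowed: %s)",
                    col, paste(bad, collapse = ", "),
                    paste(ANNOTATION_VOCAB[[col]], collapse = ", ")))
    df[[col]] <- v
  }
  if ("infiltration_category" %in% names(df)) {
    v <- df$infiltration_category
    v[v == "unknown"] <- NA
    df$infiltration_category <- factor(v, levels = INFILTRATION_LEVELS,
                                       ordered = TRUE)
  }
  if ("survival_time" %in% names(df)) {
    df$survival_time <- as.numeric(df$survival_time)
    if (any(df$survival_time < 0, na.rm = TRUE))
      stop2("negative survival_time")
  }
  if ("event" %in% names(df)) {
    df$event <- as.integer(df$event)
    if (!all(df$event %in% c(0L, 1L, NA)))
      stop2("event must be 0 (censored) or 1 (event)")
  }
  class(df) <- c("CohortAnnotation", "data.frame")
  df
}

#' Read a cohort annotation TSV
#' @param path TSV path with a header row.
#' @return a `CohortAnnotation` data.frame (see [cohort_annotation()]).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_annotation(df)
}

#' Write a cohort annotation TSV
#' @param ann a `CohortAnnotation` or plain data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- as.data.frame(ann)
  if ("infiltration_category" %in% names(out))
    out$infiltration_category <- as.character(out$infiltration_category)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
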