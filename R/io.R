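#' Read a gene x sample expression matrix from delimited text
#'
#' Expects a header row of sample ids, a first column of gene ids (header
#' cell `gene_id` by convention) and a numeric body on the log2 scale. The
#' delimiter is tab by default and auto-detected from the file extension:
#' `.csv` switches to comma. No log transform is applied on read; inputs
#' are assumed already log2.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field delimiter; `NULL` (default) picks `","` for `.csv`
#'   and `"\t"` otherwise.
#' @param class,series optional per-sample annotations passed straight to
#'   [CovExperiment()]; by default samples get placeholder class `"?"`
#'   and a single series, to be filled by [attachAnnotations()].
#' @return A [CovExperiment].
#' @seealso [writeExpressionMatrix()], [attachAnnotations()]
#' @export
readExpressionMatrix <- function(path, sep = NULL, class = NULL,
                                 series = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("missing header or no sample columns in ", path)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (gene %s), column %d (sample %s)",
                 bad[1], gene_ids[bad[1]], bad[2], colnames(body)[bad[2]]))
  }
  dimnames(vals) <- list(gene_ids, colnames(body))
  if (is.null(class)) class <- rep("?", ncol(vals))
  if (is.null(series)) series <- rep("S1", ncol(vals))
  CovExperiment(vals, class = class, series = series)
}

#' Write an expression matrix as delimited text
#'
#' Values are serialized with 17 significant digits so that
#' `readExpressionMatrix(writeExpressionMatrix(x))` reproduces gene ids,
#' sample ids and values bit-for-bit.
#'
#' @param x a [CovExperiment].
#' @param path output path; `.csv` extension writes comma-separated,
#'   anything else tab-separated (overridable via `sep`).
#' @param sep field delimiter; `NULL` auto-detects as in
#'   [readExpressionMatrix()].
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path, sep = NULL) {
  stopifnot(is(x, "CovExperiment"))
  validObject(x)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- exprsValues(x)
  header <- paste(c("gene_id", colnames(v)), collapse = sep)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = sep)
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' A TSV/CSV with columns `sample_id`, `class`, `series` (extra columns
#' are kept but ignored by the pipeline).
#'
#' @inheritParams readExpressionMatrix
#' @return A data.frame with at least the three required columns.
#' @export
readSampleAnnotations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "series")
  if (!all(need %in% colnames(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation table: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "))
  if (any(!nzchar(ann$class)) || anyNA(ann$class))
    stop("class labels must be non-empty")
  ann
}

#' Attach class and series annotations to an expression matrix
#'
#' Labels are matched by `sample_id` and applied in the matrix's sample
#' order, so the annotation table may come in any row order. Annotations
#' for samples absent from the matrix are ignored with a warning; samples
#' missing from the annotation raise an error naming them.
#'
#' @param x a [CovExperiment].
#' @param ann a data.frame as returned by [readSampleAnnotations()].
#' @return `x` with `class` and `series` colData replaced.
#' @export
attachAnnotations <- function(x, ann) {
  stopifnot(is(x, "CovExperiment"))
  ids <- colnames(x)
  missing <- setdiff(ids, ann$sample_id)
  if (length(missing))
    stop("samples missing from annotation: ", paste(missing, collapse = ", "))
  extra <- setdiff(ann$sample_id, ids)
  if (length(extra))
    warning("annotations for unknown samples ignored: ",
            paste(extra, collapse = ", "))
  idx <- match(ids, ann$sample_id)
  colData(x)$class <- as.character(ann$class[idx])
  colData(x)$series <- as.character(ann$series[idx])
  validObject(x)
  x
}
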