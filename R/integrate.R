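#' Merge expression series on their shared genes
#'
#' Restricts every matrix to the intersection of all gene sets (in the
#' first matrix's gene order) and concatenates samples in input order.
#' Class labels and series ids travel with their samples. Genes missing
#' from any platform are dropped, never imputed, so downstream
#' normalization never sees missing values.
#'
#' @param xs list of two or more [CovExperiment] objects with
#'   pairwise-disjoint sample ids.
#' @return A merged [CovExperiment].
#' @export
mergeByGene <- function(xs) {
  if (length(xs) < 2L) stop("need at least 2 matrices to merge")
  stopifnot(all(vapply(xs, is, logical(1), "CovExperiment")))
  ids <- unlist(lapply(xs, colnames))
  if (anyDuplicated(ids))
    stop("duplicated sample id across matrices: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  shared <- Reduce(intersect, lapply(xs, rownames))
  if (!length(shared))
    stop("empty gene intersection; per-matrix gene counts: ",
         paste(vapply(xs, nrow, integer(1)), collapse = ", "))
  shared <- rownames(xs[[1]])[rownames(xs[[1]]) %in% shared]
  vals <- do.call(cbind, lapply(xs, function(m) exprsValues(m)[shared, ,
                                                               drop = FALSE]))
  CovExperiment(vals,
                class = unlist(lapply(xs, classLabels)),
                series = unlist(lapply(xs, seriesIds)))
}

.quantileNormalizeMatrix <- function(v) {
  ref <- rowMeans(apply(v, 2, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j], ties.method = "average")
    # tied values receive the mean of the reference quantiles they span
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

#' Jointly quantile-normalize a merged expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the row-wise mean of the column-sorted input: afterwards every
#' column's sorted value vector is identical, so any affine or monotone
#' per-series distortion in dynamic range or offset is removed while each
#' column's rank order of genes is preserved. Tied values within a column
#' receive the mean of the reference quantiles they span.
#'
#' @param x a [CovExperiment] with at least 2 samples and no missing
#'   values.
#' @return The normalized [CovExperiment].
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "CovExperiment"))
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  v <- exprsValues(x)
  if (anyNA(v)) stop("missing values are not allowed")
  assay(x, "exprs") <- .quantileNormalizeMatrix(v)
  x
}
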