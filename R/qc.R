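#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The sup-distance between the empirical CDFs of two samples, evaluated
#' exactly at every distinct observed value (correct in the presence of
#' ties, which arise when a sample is compared against a pool that
#' includes itself). Symmetric in its arguments.
#'
#' @param a,b non-empty finite numeric vectors.
#' @return A value in `[0, 1]`.
#' @examples
#' ksStatistic(c(0, 0, 0), c(1, 1, 1))  # disjoint supports: 1
#' @export
ksStatistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("both vectors must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("both vectors must be finite")
  v <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(v)
  Fb <- stats::ecdf(b)(v)
  max(abs(Fa - Fb))
}

#' Flag outlier samples per series by KS distance to the pooled data
#'
#' For each series separately, computes the KS statistic `Ka` between
#' every sample's expression distribution and the pooled distribution of
#' all samples in that series (including the tested sample by default),
#' then flags samples whose `Ka` exceeds the boxplot fence
#' `Q3 + fence * IQR` of the per-series `Ka` values. This is the quality
#' screen applied per series before merging.
#'
#' @param x a [CovExperiment] with at least 3 samples per series.
#' @param fence multiplier of the IQR above the third quartile
#'   (default 1.5).
#' @param excludeSelf if `TRUE`, each sample is compared against the pool
#'   of the *other* samples in its series (leave-one-out pooling).
#' @return A data.frame with columns `sample_id`, `series`, `Ka`,
#'   `threshold`, `flagged`.
#' @export
detectOutliers <- function(x, fence = 1.5, excludeSelf = FALSE) {
  stopifnot(is(x, "CovExperiment"))
  ser <- seriesIds(x)
  if (any(table(ser) < 3L))
    stop("outlier rule undefined for series with fewer than 3 samples: ",
         paste(names(which(table(ser) < 3L)), collapse = ", "))
  v <- exprsValues(x)
  out <- lapply(unique(ser), function(id) {
    cols <- which(ser == id)
    pool_all <- as.vector(v[, cols])
    ka <- vapply(cols, function(j) {
      pool <- if (excludeSelf) as.vector(v[, setdiff(cols, j)]) else pool_all
      ksStatistic(v[, j], pool)
    }, numeric(1))
    thr <- stats::quantile(ka, 0.75, names = FALSE) +
      fence * stats::IQR(ka)
    data.frame(sample_id = colnames(v)[cols], series = id, Ka = ka,
               threshold = thr, flagged = ka > thr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop samples flagged by the outlier screen
#'
#' @param x a [CovExperiment].
#' @param report output of [detectOutliers()] on `x`.
#' @return `x` without the flagged samples.
#' @export
removeOutliers <- function(x, report) {
  keep <- setdiff(colnames(x), report$sample_id[report$flagged])
  x[, keep]
}
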