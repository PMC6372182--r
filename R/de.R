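#' Maximum coverage: the number of unordered class pairs
#'
#' With `N` classes, a gene can at most discriminate `(N^2 - N) / 2`
#' one-against-one class comparisons; this bound caps the coverage
#' statistic computed by [computeCoverage()]. For the five-class leukemia
#' setting (HBM/AML/ALL/CML/CLL) it equals 10.
#'
#' @param nClasses integer >= 2.
#' @return Integer `(N^2 - N) / 2`.
#' @examples
#' covMax(5)  # 10
#' @export
covMax <- function(nClasses) {
  nClasses <- as.integer(nClasses)
  if (is.na(nClasses) || nClasses < 2L) stop("need at least 2 classes")
  (nClasses * (nClasses - 1L)) %/% 2L
}

#' Fit the multiclass group-means model
#'
#' Per gene: class means `mu_{g,c}` and the pooled within-class residual
#' variance `s_g^2 = sum_c sum_{s in c} (x - mu_{g,c})^2 / d` with shared
#' residual degrees of freedom `d = n_total - n_classes`.
#'
#' @param x a [CovExperiment]; every class must have at least 2 samples
#'   and `n_total > n_classes`.
#' @return A [GroupFit-class].
#' @export
fitClassMeans <- function(x) {
  stopifnot(is(x, "CovExperiment"))
  cls <- classLabels(x)
  tab <- table(cls)
  if (any(tab < 2L))
    stop("class with fewer than 2 samples: ",
         paste(names(which(tab < 2L)), collapse = ", "))
  classes <- names(tab)
  v <- exprsValues(x)
  n <- as.integer(tab)
  names(n) <- classes
  df <- ncol(v) - length(classes)
  means <- vapply(classes, function(cl)
    rowMeans(v[, cls == cl, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) means <- matrix(means, nrow = 1L,
                                     dimnames = list(rownames(v), classes))
  resid_ss <- rowSums((v - means[, match(cls, classes), drop = FALSE])^2)
  new("GroupFit", means = means, s2 = resid_ss / df, df = df, n = n)
}

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0`; the workhorse of the
#' moment-matching prior-df estimate in [moderateVariances()].
#'
#' @param x positive numeric vector.
#' @return `y` with `trigamma(y) = x`; `Inf` where `x <= 0`.
#' @keywords internal
trigammaInverse <- function(x) {
  y <- ifelse(x > 1e7, 1 / sqrt(x), 0.5 + 1 / x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] <= 0) { out[i] <- Inf; next }
    if (x[i] > 1e7) { out[i] <- 1 / sqrt(x[i]); next }
    if (x[i] < 1e-6) { out[i] <- 1 / x[i]; next }
    yi <- y[i]
    for (iter in 1:50) {
      tri <- trigamma(yi)
      dif <- tri * (1 - tri / x[i]) / psigamma(yi, 2)
      yi <- yi + dif
      if (-dif / yi < 1e-8) break
    }
    out[i] <- yi
  }
  out
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits a scaled inverse-chi-square prior `(d0, s02)` to the observed
#' residual variances by matching the first two moments of `log(s_g^2)`
#' against its theoretical scaled-F form via digamma/trigamma relations,
#' then shrinks each gene's variance to the posterior
#' `s2post = (d0 * s02 + d * s_g^2) / (d0 + d)`. When the log-variances
#' show no excess dispersion beyond sampling noise, `d0 = Inf` and every
#' posterior variance equals the common prior value.
#'
#' @param fit a [GroupFit-class] with at least 2 genes of positive
#'   variance.
#' @param d0 optional prior df override: `0` disables moderation
#'   (`s2post = s_g^2` exactly); `Inf` forces complete pooling.
#' @return An [EBayesParams-class].
#' @export
moderateVariances <- function(fit, d0 = NULL) {
  stopifnot(is(fit, "GroupFit"))
  s2 <- fit@s2
  d <- fit@df
  pos <- s2 > 0
  if (!is.null(d0) && d0 == 0)
    return(new("EBayesParams", d0 = 0, s02 = NA_real_, s2post = s2))
  if (sum(pos) < 2L)
    stop("need >= 2 genes with positive variance (degenerate, ",
         "noise-free input)")
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(d / 2)
  if (is.null(d0)) {
    if (evar > 0) {
      d0 <- 2 * trigammaInverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf  # no excess dispersion beyond sampling noise
      s02 <- mean(s2[pos])
    }
  } else {
    s02 <- if (is.finite(d0))
      exp(emean + digamma(d0 / 2) - log(d0 / 2)) else mean(s2[pos])
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + d * s2) / (d0 + d)
  new("EBayesParams", d0 = d0, s02 = s02, s2post = s2post)
}

#' All pairwise class contrasts with moderated t-statistics
#'
#' For every unordered class pair `(i, j)` and gene `g`:
#' `lfc = mu_{g,i} - mu_{g,j}`,
#' `t = lfc / sqrt(s2post_g * (1/n_i + 1/n_j))`, and a two-sided p-value
#' on `d0 + d` degrees of freedom. With `d0 = 0` the statistic reduces to
#' the classical two-sample t built from the multiclass pooled variance.
#'
#' @param fit a [GroupFit-class].
#' @param eb an [EBayesParams-class] from [moderateVariances()].
#' @return A [PairwiseStats-class].
#' @export
pairwiseStats <- function(fit, eb) {
  stopifnot(is(fit, "GroupFit"), is(eb, "EBayesParams"))
  classes <- colnames(fit@means)
  nc <- length(classes)
  cmb <- utils::combn(nc, 2)
  pairs <- cbind(classes[cmb[1, ]], classes[cmb[2, ]])
  dfTotal <- eb@d0 + fit@df
  s2 <- eb@s2post
  s2[s2 <= 0] <- .Machine$double.eps  # guard for noise-free fixtures
  lfc <- fit@means[, cmb[1, ], drop = FALSE] -
    fit@means[, cmb[2, ], drop = FALSE]
  inv_n <- 1 / fit@n[cmb[1, ]] + 1 / fit@n[cmb[2, ]]
  tstat <- sweep(lfc / sqrt(s2), 2, sqrt(inv_n), "/")
  p <- 2 * pt(-abs(tstat), df = dfTotal)
  p[p <= 0] <- .Machine$double.xmin
  cn <- paste(pairs[, 1], pairs[, 2], sep = ".vs.")
  dimnames(lfc) <- dimnames(tstat) <- dimnames(p) <-
    list(rownames(fit@means), cn)
  new("PairwiseStats", pairs = pairs, lfc = lfc, t = tstat, p = p,
      dfTotal = dfTotal, nClasses = as.integer(nc))
}

#' Coverage: the number of class pairs a gene discriminates
#'
#' A gene's coverage (COV) is the number of unordered class-pair
#' comparisons for which it simultaneously satisfies
#' `|lfc| >= lfcThreshold` and `p <= pThreshold`; its range is
#' `[0, covMax(N)]`.
#'
#' @param ps a [PairwiseStats-class].
#' @param lfcThreshold positive log-fold-change threshold (log2 units).
#' @param pThreshold p-value gate in `(0, 1)`; the study default is a raw
#'   (unadjusted) 0.001.
#' @param adjust `"none"` (default, per the selection rule) or `"BH"` for
#'   Benjamini-Hochberg adjustment of each pair's p-values across genes
#'   before gating.
#' @return Named integer vector of per-gene COV values.
#' @export
computeCoverage <- function(ps, lfcThreshold, pThreshold,
                            adjust = c("none", "BH")) {
  stopifnot(is(ps, "PairwiseStats"))
  adjust <- match.arg(adjust)
  if (lfcThreshold <= 0) stop("lfcThreshold must be positive")
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  p <- ps@p
  if (adjust == "BH") p <- apply(p, 2, stats::p.adjust, method = "BH")
  cov <- rowSums(abs(ps@lfc) >= lfcThreshold & p <= pThreshold)
  storage.mode(cov) <- "integer"
  cov
}

#' Select differentially expressed genes by the (LFC, p, COV) triple rule
#'
#' Keeps genes whose coverage reaches `covThreshold` and summarises each
#' over its *covered* pairs (the pairs passing both per-pair gates):
#' mean absolute moderated t, mean p-value, mean absolute LFC. The
#' default thresholds (LFC >= 2.5, p <= 0.001, COV >= 5) are the
#' operating point selected for the five-class leukemia study.
#'
#' @inheritParams computeCoverage
#' @param covThreshold integer in `[1, covMax(N)]`.
#' @return A data.frame (`gene_id`, `cov`, `mean_abs_t`, `mean_p`,
#'   `mean_abs_lfc`) sorted by COV descending, then mean |t| descending,
#'   ties broken by gene id.
#' @export
selectDEGs <- function(ps, lfcThreshold = 2.5, pThreshold = 0.001,
                       covThreshold = 5L, adjust = c("none", "BH")) {
  stopifnot(is(ps, "PairwiseStats"))
  adjust <- match.arg(adjust)
  cmax <- covMax(ps@nClasses)
  if (covThreshold < 1L || covThreshold > cmax)
    stop("covThreshold must lie in [1, ", cmax, "]")
  p <- ps@p
  if (adjust == "BH") p <- apply(p, 2, stats::p.adjust, method = "BH")
  covered <- abs(ps@lfc) >= lfcThreshold & p <= pThreshold
  cov <- rowSums(covered)
  keep <- which(cov >= covThreshold)
  summ <- function(mat, i) mean(mat[i, covered[i, ]])
  res <- data.frame(
    gene_id = rownames(ps@lfc)[keep],
    cov = as.integer(cov[keep]),
    mean_abs_t = vapply(keep, function(i) summ(abs(ps@t), i), numeric(1)),
    mean_p = vapply(keep, function(i) summ(p, i), numeric(1)),
    mean_abs_lfc = vapply(keep, function(i) summ(abs(ps@lfc), i),
                          numeric(1)),
    stringsAsFactors = FALSE)
  res <- res[order(-res$cov, -res$mean_abs_t, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the integration and DEG-extraction chain
#'
#' Convenience wrapper over the full pre-classification pipeline:
#' per-series outlier screening ([detectOutliers()]), removal of flagged
#' samples, merge on shared genes ([mergeByGene()]), joint quantile
#' normalization ([quantileNormalize()]), the multiclass group-means fit
#' with empirical-Bayes moderation, and the (LFC, p, COV) selection.
#'
#' @param xs a single [CovExperiment] (split internally by series) or a
#'   list of per-series experiments.
#' @inheritParams selectDEGs
#' @param qcFence boxplot fence for [detectOutliers()]; `NULL` skips QC.
#' @return List with `experiment` (the normalized merged matrix),
#'   `qc` (the outlier report or `NULL`), `pairwise`
#'   (a [PairwiseStats-class]) and `degs` (the [selectDEGs()] table).
#' @export
runPipeline <- function(xs, lfcThreshold = 2.5, pThreshold = 0.001,
                        covThreshold = 5L, qcFence = 1.5) {
  if (is(xs, "CovExperiment")) xs <- splitBySeries(xs)
  qc <- NULL
  if (!is.null(qcFence)) {
    qc <- do.call(rbind, lapply(xs, detectOutliers, fence = qcFence))
    rownames(qc) <- NULL
    xs <- lapply(xs, function(m) removeOutliers(m, qc))
  }
  merged <- if (length(xs) > 1L) mergeByGene(xs) else xs[[1]]
  norm <- quantileNormalize(merged)
  fit <- fitClassMeans(norm)
  eb <- moderateVariances(fit)
  ps <- pairwiseStats(fit, eb)
  degs <- selectDEGs(ps, lfcThreshold = lfcThreshold,
                     pThreshold = pThreshold, covThreshold = covThreshold)
  list(experiment = norm, qc = qc, pairwise = ps, degs = degs)
}
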