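#' @importFrom methods setClass setValidity new validObject is slot callNextMethod
#' @importFrom stats median sd var pt pf quantile rnorm rchisq setNames predict
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' CovExperiment: a multi-series, multiclass expression container
#'
#' `CovExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a genes x samples matrix of log2-scale expression values together
#' with the two per-sample annotations the pipeline needs: a disease-state
#' `class` (e.g. HBM/AML/ALL/CML/CLL) and a `series` (batch/platform)
#' identifier. Validity enforces what every downstream stage assumes:
#' unique gene and sample identifiers, finite values, at least one gene and
#' one sample, and class/series labels for every sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 expression scale.
#' @param class character or factor of per-sample class labels, length
#'   `ncol(values)`. May be `NA`-free empty strings are rejected.
#' @param series character or factor of per-sample series/batch ids,
#'   length `ncol(values)`. Defaults to a single series `"S1"`.
#'
#' @return A `CovExperiment` object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ce <- CovExperiment(m, class = c("A", "A", "B", "B"))
#' classLabels(ce)
#' @export
CovExperiment <- function(values, class, series = rep("S1", ncol(values))) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (gene ids) and colnames (sample ids)")
  se <- SummarizedExperiment(
    assays  = list(exprs = values),
    colData = DataFrame(class  = as.character(class),
                        series = as.character(series),
                        row.names = colnames(values)))
  new("CovExperiment", se)
}

setClass("CovExperiment", contains = "SummarizedExperiment")

setValidity("CovExperiment", function(object) {
  msg <- character()
  v <- assay(object)
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "empty matrices are rejected: need >= 1 gene and >= 1 sample")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate gene id: %s",
                          paste(unique(rownames(object)[duplicated(rownames(object))]),
                                collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique and non-NULL")
  if (!all(is.finite(v)))
    msg <- c(msg, "all expression values must be finite")
  cd <- colData(object)
  if (!all(c("class", "series") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'class' and 'series' columns")
  } else {
    if (anyNA(cd$class) || any(!nzchar(cd$class)))
      msg <- c(msg, "every sample needs a non-empty class label")
    if (anyNA(cd$series) || any(!nzchar(cd$series)))
      msg <- c(msg, "every sample needs a non-empty series id")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for CovExperiment annotations
#'
#' @param x a `CovExperiment`.
#' @return `classLabels` and `seriesIds` return character vectors of
#'   per-sample labels; `exprsValues` returns the genes x samples numeric
#'   matrix.
#' @examples
#' m <- matrix(0, 2, 2, dimnames = list(c("G1", "G2"), c("S1", "S2")))
#' ce <- CovExperiment(m, class = c("A", "B"))
#' seriesIds(ce)
#' @export
classLabels <- function(x) as.character(colData(x)$class)

#' @rdname classLabels
#' @export
seriesIds <- function(x) as.character(colData(x)$series)

#' @rdname classLabels
#' @export
exprsValues <- function(x) assay(x, "exprs")

#' Split a CovExperiment by series
#'
#' Returns one `CovExperiment` per series id, in order of first appearance;
#' the inverse of [mergeByGene()] on series with a shared gene set.
#'
#' @param x a `CovExperiment`.
#' @return Named list of `CovExperiment` objects.
#' @export
splitBySeries <- function(x) {
  s <- seriesIds(x)
  lapply(setNames(nm = unique(s)), function(id) x[, s == id])
}

setMethod("show", "CovExperiment", function(object) {
  cat("CovExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  classes:",
      paste(sprintf("%s(%d)", names(table(classLabels(object))),
                    table(classLabels(object))), collapse = " "), "\n")
  cat("  series: ", paste(unique(seriesIds(object)), collapse = " "), "\n")
})

#' GroupFit: per-gene multiclass group-means fit
#'
#' Holds, for every gene, the class means on the log2 scale, the pooled
#' within-class residual variance, the shared residual degrees of freedom
#' `n_total - n_classes`, and the per-class sample sizes. Produced by
#' [fitClassMeans()].
#'
#' @slot means numeric matrix, genes x classes, of class-mean log2 values.
#' @slot s2 numeric vector of pooled within-class variances, one per gene.
#' @slot df residual degrees of freedom (scalar, shared across genes).
#' @slot n named integer vector of per-class sample sizes.
#' @export
setClass("GroupFit",
         representation(means = "matrix", s2 = "numeric",
                        df = "numeric", n = "integer"))

setValidity("GroupFit", function(object) {
  msg <- character()
  if (object@df < 1) msg <- c(msg, "residual df must be >= 1")
  if (any(object@s2 < 0)) msg <- c(msg, "residual variances must be >= 0")
  if (length(object@s2) != nrow(object@means))
    msg <- c(msg, "one variance per gene required")
  if (ncol(object@means) != length(object@n))
    msg <- c(msg, "class means and class sizes disagree on class count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroupFit", function(object) {
  cat("GroupFit:", nrow(object@means), "genes,", ncol(object@means),
      "classes, residual df =", object@df, "\n")
})

#' EBayesParams: empirical-Bayes variance moderation parameters
#'
#' The inverse-chi-square prior fitted to the per-gene residual variances:
#' prior degrees of freedom `d0` (may be `Inf`), prior variance `s02`, and
#' the resulting posterior (shrunken) variances
#' `s2post = (d0 * s02 + df * s2) / (d0 + df)`. Produced by
#' [moderateVariances()].
#'
#' @slot d0 prior degrees of freedom (>= 0, possibly `Inf`).
#' @slot s02 prior variance (> 0; `NA` permitted when `d0 = 0`, where the
#'   prior carries no weight).
#' @slot s2post numeric vector of posterior variances, one per gene.
#' @export
setClass("EBayesParams",
         representation(d0 = "numeric", s02 = "numeric", s2post = "numeric"))

setValidity("EBayesParams", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
    msg <- c(msg, "d0 must be a single value >= 0")
  if (length(object@s02) != 1L)
    msg <- c(msg, "s02 must be a single value")
  if (!is.na(object@s02) && object@s02 <= 0 && object@d0 > 0)
    msg <- c(msg, "s02 must be > 0 when the prior has weight")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EBayesParams", function(object) {
  cat("EBayesParams: d0 =", object@d0, ", s02 =", signif(object@s02, 4),
      ",", length(object@s2post), "posterior variances\n")
})

#' PairwiseStats: all pairwise class contrasts per gene
#'
#' For each of the `(N^2 - N) / 2` unordered class pairs and every gene:
#' the log-fold change (difference of class means), the moderated
#' t-statistic `lfc / sqrt(s2post * (1/n_i + 1/n_j))`, and the two-sided
#' p-value on `d0 + df` degrees of freedom. Produced by [pairwiseStats()].
#'
#' @slot pairs two-column character matrix of unordered class pairs.
#' @slot lfc genes x pairs matrix of log-fold changes.
#' @slot t genes x pairs matrix of moderated t-statistics.
#' @slot p genes x pairs matrix of two-sided p-values.
#' @slot dfTotal total degrees of freedom used for the t distribution.
#' @slot nClasses number of classes.
#' @export
setClass("PairwiseStats",
         representation(pairs = "matrix", lfc = "matrix", t = "matrix",
                        p = "matrix", dfTotal = "numeric",
                        nClasses = "integer"))

setValidity("PairwiseStats", function(object) {
  msg <- character()
  n <- object@nClasses
  if (nrow(object@pairs) != covMax(n))
    msg <- c(msg, "number of pairs must equal (N^2 - N) / 2")
  dims <- list(dim(object@lfc), dim(object@t), dim(object@p))
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "lfc, t and p matrices must share dimensions")
  if (any(object@p <= 0 | object@p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(sign(object@t) * sign(object@lfc) < 0))
    msg <- c(msg, "t and lfc must share sign")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairwiseStats", function(object) {
  cat("PairwiseStats:", nrow(object@lfc), "genes x", nrow(object@pairs),
      "class pairs (", object@nClasses, "classes ), df =",
      object@dfTotal, "\n")
})

#' @rdname PairwiseStats-class
#' @param ps a `PairwiseStats` object.
#' @return `pairNames` returns a character vector like `"A.vs.B"`.
#' @export
pairNames <- function(ps) paste(ps@pairs[, 1], ps@pairs[, 2], sep = ".vs.")
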