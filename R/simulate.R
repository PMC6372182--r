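#' Describe a synthetic multi-series, multiclass expression study
#'
#' Builds a validated design object for [simulateDataset()]. Values are
#' generated on the log2 scale as
#' `x = scale_series * (baseline + mu_{gene,class} + eps) + offset_series`
#' with `eps ~ N(0, noiseSd^2)`: Gaussian noise on the log2 scale (the
#' modelling assumption of moderated t-statistics) and affine per-series
#' batch effects, which joint quantile normalization is able to remove.
#'
#' Planted genes carry a class-mean vector `mu` (log2 units); all other
#' genes are null (identical means across classes). Samples of each class
#' are distributed across series round-robin, so every series sees every
#' class in near-equal proportion.
#'
#' @param nClasses number of classes (>= 2).
#' @param samplesPerClass integer vector of per-class sample counts
#'   (may be unbalanced).
#' @param nGenes total number of genes.
#' @param plantedMu numeric matrix with one row per planted gene and
#'   `nClasses` columns of class means (log2 units); may have 0 rows.
#' @param noiseSd positive noise standard deviation (log2 units).
#' @param seriesOffset,seriesScale per-series additive offsets and
#'   multiplicative scales; equal lengths define the number of series.
#' @param baselineMean baseline log2 expression added to every value.
#' @param baselineGeneSd standard deviation of per-gene baseline offsets
#'   around `baselineMean` (log2 units; default 0, i.e. a common
#'   baseline). A positive value spreads the null genes over a realistic
#'   dynamic range, giving the pooled distribution density everywhere a
#'   planted value can fall.
#' @param classNames,seed class labels and RNG seed.
#' @return A list of class `SimulationDesign`.
#' @export
simulationDesign <- function(nClasses = 5L,
                             samplesPerClass = c(26L, 80L, 60L, 53L, 29L),
                             nGenes = 2000L,
                             plantedMu = matrix(numeric(0), 0, nClasses),
                             noiseSd = 0.5,
                             seriesOffset = c(0, 2),
                             seriesScale = c(1, 1.1),
                             baselineMean = 6,
                             baselineGeneSd = 0,
                             classNames = NULL,
                             seed = 1L) {
  if (nClasses < 2L) stop("need at least 2 classes")
  if (length(samplesPerClass) != nClasses)
    stop("samplesPerClass must have one entry per class")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (baselineGeneSd < 0) stop("baselineGeneSd must be >= 0")
  if (length(seriesOffset) != length(seriesScale))
    stop("seriesOffset and seriesScale must have equal length")
  if (ncol(plantedMu) != nClasses && nrow(plantedMu) > 0)
    stop("class-mean vectors must have length nClasses")
  if (nrow(plantedMu) > nGenes) stop("more planted genes than genes")
  if (is.null(classNames))
    classNames <- if (nClasses == 5L) c("HBM", "AML", "ALL", "CML", "CLL")
                  else paste0("C", seq_len(nClasses))
  structure(list(nClasses = as.integer(nClasses),
                 samplesPerClass = as.integer(samplesPerClass),
                 nGenes = as.integer(nGenes),
                 plantedMu = plantedMu,
                 noiseSd = noiseSd,
                 seriesOffset = seriesOffset,
                 seriesScale = seriesScale,
                 baselineMean = baselineMean,
                 baselineGeneSd = baselineGeneSd,
                 classNames = classNames,
                 seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Ground-truth coverage of a planted class-mean vector
#'
#' The infinite-sample oracle for [computeCoverage()]: the number of
#' unordered class pairs `(i, j)` whose true mean difference satisfies
#' `|mu_i - mu_j| >= lfcThreshold`.
#'
#' @param mu numeric vector of class means (log2 units).
#' @param lfcThreshold positive log-fold-change threshold.
#' @return Integer count in `[0, covMax(length(mu))]`.
#' @examples
#' plantedCov(c(0, 3, 0, 0, 0), 2.5)  # one class against four: 4
#' plantedCov(c(0, 0, 3, 3, 3), 2.5)  # 2 x 3 cross pairs: 6
#' @export
plantedCov <- function(mu, lfcThreshold) {
  if (lfcThreshold <= 0) stop("lfcThreshold must be positive")
  d <- abs(outer(mu, mu, "-"))
  sum(d[upper.tri(d)] >= lfcThreshold)
}

#' Simulate a multi-series, multiclass expression dataset
#'
#' Generates data under the model documented in [simulationDesign()].
#' The same design (including its `seed`) yields bit-identical output.
#'
#' @param design a `SimulationDesign` from [simulationDesign()].
#' @param lfcThreshold threshold at which the ground-truth expected COV of
#'   each planted gene is computed (default 2.5).
#' @return A list with elements `experiment` (a [CovExperiment]) and
#'   `truth` (data.frame: `gene_id`, `expected_cov`, `is_null`).
#' @export
simulateDataset <- function(design, lfcThreshold = 2.5) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(design$seed)
  nc <- design$nClasses
  n <- sum(design$samplesPerClass)
  ns <- length(design$seriesOffset)
  cls <- rep(design$classNames, design$samplesPerClass)
  # round-robin within class -> every series sees every class
  series_idx <- unlist(lapply(design$samplesPerClass,
                              function(k) ((seq_len(k) - 1L) %% ns) + 1L))
  mu <- matrix(0, design$nGenes, nc)
  npl <- nrow(design$plantedMu)
  if (npl > 0) mu[seq_len(npl), ] <- design$plantedMu
  class_idx <- match(cls, design$classNames)
  baseline <- design$baselineMean +
    if (design$baselineGeneSd > 0)
      rnorm(design$nGenes, sd = design$baselineGeneSd) else 0
  signal <- baseline + mu[, class_idx, drop = FALSE]
  eps <- matrix(rnorm(design$nGenes * n, sd = design$noiseSd),
                design$nGenes, n)
  x <- sweep(sweep(signal + eps, 2, design$seriesScale[series_idx], "*"),
             2, design$seriesOffset[series_idx], "+")
  gene_ids <- sprintf("G%04d", seq_len(design$nGenes))
  dimnames(x) <- list(gene_ids, sprintf("S%03d", seq_len(n)))
  ce <- CovExperiment(x, class = cls,
                      series = paste0("SER", series_idx))
  expected <- integer(design$nGenes)
  if (npl > 0)
    expected[seq_len(npl)] <- apply(design$plantedMu, 1, plantedCov,
                                    lfcThreshold = lfcThreshold)
  truth <- data.frame(gene_id = gene_ids,
                      expected_cov = expected,
                      is_null = seq_len(design$nGenes) > npl,
                      stringsAsFactors = FALSE)
  list(experiment = ce, truth = truth)
}

#' The package's default desk-scale study design
#'
#' Five classes with the unbalanced sizes 26/80/60/53/29, 2000 genes of
#' which 50 are planted with effect-size step `delta = 3.0` log2 units,
#' noise sd 0.5, and two series with affine batch effects (offsets 0/+2,
#' scales 1/1.1).
#'
#' Each planted gene draws one of six fixed level multisets (coverage
#' 6, 7, 8, 9 or 10 at LFC threshold 2.5, with the low-coverage patterns
#' most frequent, as observed for real multiclass DEG panels), centers it
#' to mean zero, scales it by `delta`, and assigns levels to classes by a
#' random permutation. The permutation makes the planting
#' class-exchangeable: every class has the same marginal distribution of
#' planted values, so joint quantile normalization (which assumes
#' comparable distributions across samples) does not erode the planted
#' log-fold changes.
#'
#' @param seed RNG seed; drives both the planted patterns and the noise.
#' @param nGenes,nPlanted,delta,noiseSd,samplesPerClass overrides of the
#'   defaults above.
#' @return A `SimulationDesign`.
#' @export
defaultDesign <- function(seed = 1L, nGenes = 2000L, nPlanted = 50L,
                          delta = 3.0, noiseSd = 0.5,
                          samplesPerClass = c(26L, 80L, 60L, 53L, 29L)) {
  set.seed(seed)
  patterns <- list(c(0, 0, 0, 1, 1),   # COV 6
                   c(0, 0, 1, 1, 1),   # COV 6
                   c(0, 0, 0, 1, 2),   # COV 7
                   c(0, 0, 1, 1, 2),   # COV 8
                   c(0, 0, 1, 2, 3),   # COV 9
                   c(0, 1, 2, 3, 4))   # COV 10
  weights <- c(0.25, 0.25, 0.2, 0.15, 0.1, 0.05)
  mu <- matrix(0, nPlanted, 5L)
  for (i in seq_len(nPlanted)) {
    lv <- patterns[[sample.int(6L, 1L, prob = weights)]]
    mu[i, ] <- delta * sample(lv - mean(lv))
  }
  simulationDesign(nClasses = 5L, samplesPerClass = samplesPerClass,
                   nGenes = nGenes, plantedMu = mu, noiseSd = noiseSd,
                   seriesOffset = c(0, 2), seriesScale = c(1, 1.1),
                   baselineMean = 8, baselineGeneSd = 2, seed = seed)
}
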