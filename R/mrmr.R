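#' Discretize expression into three states per gene
#'
#' Standard mRMR preprocessing for continuous expression: per gene,
#' values below `mean - kSigma * sd` become state 0, values above
#' `mean + kSigma * sd` state 2, everything else state 1. Invariant under
#' per-gene affine transforms of the input.
#'
#' @param x a [CovExperiment] or a numeric genes x samples matrix; every
#'   gene must have positive variance.
#' @param kSigma positive width of the central band in standard
#'   deviations (default 1).
#' @return Integer matrix of states in `{0, 1, 2}`, with attributes
#'   `center` and `scale` holding the per-gene parameters used.
#' @export
discretizeExpression <- function(x, kSigma = 1) {
  v <- if (is(x, "CovExperiment")) exprsValues(x) else x
  if (kSigma <= 0) stop("kSigma must be positive")
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  if (any(sdv == 0))
    stop("zero-variance gene: ",
         paste(rownames(v)[sdv == 0], collapse = ", "))
  lo <- mu - kSigma * sdv
  hi <- mu + kSigma * sdv
  d <- matrix(1L, nrow(v), ncol(v), dimnames = dimnames(v))
  d[v < lo] <- 0L
  d[v > hi] <- 2L
  attr(d, "center") <- mu
  attr(d, "scale") <- sdv
  d
}

#' Plug-in mutual information between two discrete vectors
#'
#' `I(A; B) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the joint
#' contingency table of the observed pairs. Symmetric and non-negative;
#' reported in bits.
#'
#' @param a,b vectors of equal length (any discrete coding).
#' @return Mutual information in bits.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1))  # independent: 0
#' @export
mutualInformation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (!length(a)) stop("vectors must be non-empty")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
}

#' Greedy minimum-redundancy maximum-relevance gene ranking
#'
#' Ranks genes by the MID (mutual-information difference) criterion:
#' step 1 picks the gene with maximal relevance `I(gene; class)`; each
#' subsequent step picks, among unselected genes, the maximizer of
#' `I(g; class) - mean_{s in selected} I(g; s)`. Ties at any step are
#' broken by lexicographic gene id, so the ranking is deterministic.
#'
#' @param d integer state matrix from [discretizeExpression()] (genes in
#'   rows).
#' @param classLabels per-sample class labels (length `ncol(d)`).
#' @param m number of genes to rank, `1 <= m <= nrow(d)`.
#' @return A data.frame (`rank`, `gene_id`, `score`, `relevance`): the
#'   mRMR order with each step's criterion value and each gene's
#'   relevance to the class.
#' @export
mrmrRank <- function(d, classLabels, m = nrow(d)) {
  if (length(classLabels) != ncol(d))
    stop("classLabels must have one entry per sample")
  if (m < 1L || m > nrow(d)) stop("m must lie in [1, ", nrow(d), "]")
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  ord <- order(genes)  # lexicographic; which.max picks the first maximum
  d <- d[ord, , drop = FALSE]
  genes <- genes[ord]
  relevance <- vapply(seq_len(nrow(d)), function(i)
    mutualInformation(d[i, ], classLabels), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  redundancy_sum <- numeric(nrow(d))
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(nrow(d)), selected)
    crit <- if (step == 1L) relevance[cand]
            else relevance[cand] - redundancy_sum[cand] / length(selected)
    pick <- cand[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, crit[which.max(crit)])
    if (step < m) {
      cand2 <- setdiff(seq_len(nrow(d)), selected)
      redundancy_sum[cand2] <- redundancy_sum[cand2] +
        vapply(cand2, function(i)
          mutualInformation(d[i, ], d[pick, ]), numeric(1))
    }
  }
  data.frame(rank = seq_len(m), gene_id = genes[selected],
             score = scores, relevance = relevance[selected],
             stringsAsFactors = FALSE)
}
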