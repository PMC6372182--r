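#' Scale each gene to median 0 and unit standard deviation
#'
#' The pre-classification normalization: per gene,
#' `x -> (x - median(x)) / sd(x)`. Idempotent up to floating point and
#' invariant under per-gene affine shifts of the input.
#'
#' @param x a [CovExperiment] or numeric genes x samples matrix; every
#'   gene must have positive sd.
#' @return Object of the same type, scaled.
#' @export
scaleMedianUnitSD <- function(x) {
  v <- if (is(x, "CovExperiment")) exprsValues(x) else x
  sdv <- apply(v, 1, sd)
  if (any(sdv == 0))
    stop("zero-sd gene: ", paste(rownames(v)[sdv == 0], collapse = ", "))
  med <- apply(v, 1, median)
  out <- (v - med) / sdv
  if (is(x, "CovExperiment")) { assay(x, "exprs") <- out; x } else out
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds preserving per-class proportions:
#' within each class, samples are shuffled (seeded) and dealt round-robin,
#' so every fold's per-class count is within 1 of `n_c / k`.
#' Deterministic for a given seed.
#'
#' @param classLabels per-sample class labels.
#' @param k number of folds (study default 5).
#' @param seed RNG seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratifiedFolds <- function(classLabels, k = 5L, seed = 1L) {
  tab <- table(classLabels)
  if (any(tab < k))
    stop("class smaller than k: ",
         paste(names(which(tab < k)), collapse = ", "))
  set.seed(seed)
  fold <- integer(length(classLabels))
  for (cl in names(tab)) {
    idx <- sample(which(classLabels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Confusion matrix of true versus predicted labels
#'
#' @param truth,predicted equal-length label vectors; `predicted` is
#'   coerced onto the union of the two label sets so the matrix is
#'   square.
#' @return Integer matrix, true classes in rows, predictions in columns.
#' @export
confusionMatrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  lv <- sort(unique(c(as.character(truth), as.character(predicted))))
  table(factor(truth, levels = lv), factor(predicted, levels = lv))
}

#' Macro-averaged F1 score
#'
#' Per class `c`: precision `p_c` and recall `r_c` from the confusion
#' matrix, `f1_c = 2 p_c r_c / (p_c + r_c)` (0 when `p_c + r_c = 0`);
#' the score is the unweighted mean of `f1_c` over classes, so each class
#' contributes equally regardless of its size.
#'
#' @param cm square confusion matrix (true x predicted) with at least one
#'   true sample per class.
#' @param average `"macro"` (default) or `"micro"` (pooled counts; equals
#'   accuracy for single-label classification).
#' @return A value in `[0, 1]`.
#' @export
macroF1 <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  if (!length(cm) || sum(cm) == 0) stop("empty confusion matrix")
  if (any(rowSums(cm) == 0))
    stop("every class needs at least one true sample")
  if (average == "micro") return(sum(diag(cm)) / sum(cm))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- tp / rowSums(cm)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

.trainPredict <- function(classifier, xtr, ytr, xte, seed,
                          knnK = 3L, rfTrees = 100L) {
  ytr <- factor(ytr)
  switch(classifier,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial")
      as.character(predict(fit, xte))
    },
    knn = {
      set.seed(seed)
      as.character(class::knn(xtr, xte, ytr, k = knnK))
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr)
      as.character(predict(fit, xte))
    },
    rf = {
      set.seed(seed)
      fit <- randomForest::randomForest(xtr, ytr, ntree = rfTrees)
      as.character(predict(fit, xte))
    },
    stop("unknown classifier: ", classifier))
}

#' Cross-validated assessment of a gene signature
#'
#' Restricts the matrix to the top `nGenes` of an mRMR ranking, then runs
#' stratified k-fold cross-validation with one of four classifiers.
#' Within each fold, genes are scaled to median 0 / sd 1 using
#' *training-fold* statistics only, which are then applied to the test
#' fold, so no information leaks from test to training. Out-of-fold
#' predictions are pooled into one confusion matrix from which accuracy
#' and the macro F1 score are computed (per-fold metrics are also
#' reported).
#'
#' @param x a [CovExperiment] containing at least the ranked genes.
#' @param ranking data.frame from [mrmrRank()] (or any table with a
#'   `gene_id` column in rank order).
#' @param nGenes number of top-ranked genes to use.
#' @param classifier one of `"svm"` (RBF kernel, one-vs-one voting),
#'   `"knn"` (k = 3), `"nb"` (Gaussian naive Bayes), `"rf"`
#'   (100 trees).
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment and the stochastic classifiers.
#' @param average F1 averaging passed to [macroF1()].
#' @return A list of class `covCV`: `classifier`, `nGenes`, `k`, `seed`,
#'   `accuracy`, `f1`, `foldAccuracy`, `foldF1`, `confusion`.
#' @export
evaluateSignature <- function(x, ranking, nGenes,
                              classifier = c("svm", "knn", "nb", "rf"),
                              k = 5L, seed = 1L,
                              average = c("macro", "micro")) {
  classifier <- match.arg(classifier)
  average <- match.arg(average)
  stopifnot(is(x, "CovExperiment"))
  if (nGenes > nrow(ranking))
    stop("nGenes exceeds ranking length (", nrow(ranking), ")")
  genes <- ranking$gene_id[seq_len(nGenes)]
  miss <- setdiff(genes, rownames(x))
  if (length(miss))
    stop("ranked genes absent from matrix: ", paste(miss, collapse = ", "))
  v <- exprsValues(x)[genes, , drop = FALSE]
  y <- classLabels(x)
  fold <- stratifiedFolds(y, k = k, seed = seed)
  pred <- character(length(y))
  foldAcc <- foldF1 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    med <- apply(v[, tr, drop = FALSE], 1, median)
    sdv <- apply(v[, tr, drop = FALSE], 1, sd)
    sdv[sdv == 0] <- 1  # constant-in-training gene carries no signal
    xtr <- t((v[, tr, drop = FALSE] - med) / sdv)
    xte <- t((v[, !tr, drop = FALSE] - med) / sdv)
    pf <- .trainPredict(classifier, xtr, y[tr], xte, seed = seed + f)
    pred[!tr] <- pf
    cmf <- confusionMatrix(y[!tr], pf)
    foldAcc[f] <- sum(diag(cmf)) / sum(cmf)
    foldF1[f] <- macroF1(cmf, average = average)
  }
  cm <- confusionMatrix(y, pred)
  structure(list(classifier = classifier, nGenes = nGenes, k = k,
                 seed = seed,
                 accuracy = sum(diag(cm)) / sum(cm),
                 f1 = macroF1(cm, average = average),
                 foldAccuracy = foldAcc, foldF1 = foldF1,
                 confusion = cm),
            class = "covCV")
}

#' @export
print.covCV <- function(x, ...) {
  cat(sprintf("%s, top %d genes, %d-fold CV: accuracy %.4f, F1 %.4f\n",
              x$classifier, x$nGenes, x$k, x$accuracy, x$f1))
  invisible(x)
}
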