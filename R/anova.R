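#' Type III factorial ANOVA over pipeline hyperparameters
#'
#' Fits the main-effects linear model for a response (accuracy or F1)
#' against experiment factors (e.g. classifier, LFC threshold, COV
#' threshold, number of genes) under sum-to-zero coding, and attributes a
#' Type III sum of squares to each factor by comparing the full model
#' against the model with that factor removed (the other factors kept).
#' For balanced designs this coincides with sequential sums of squares;
#' for unbalanced designs it is the marginal attribution. A constant
#' response yields all-zero sums of squares, reported with `F = 0` and
#' `p = 1`.
#'
#' @param results data.frame of runs, one row per run.
#' @param response name of the numeric response column.
#' @param factors character vector of factor column names; every factor
#'   must have at least 2 observed levels.
#' @return A data.frame with rows for each factor plus `Residuals` and
#'   `Corrected Total`, and columns `Source`, `SumSq`, `df`, `MeanSq`,
#'   `F`, `p`.
#' @export
factorialAnova <- function(results, response = "accuracy",
                           factors = c("classifier", "lfc", "cov",
                                       "n_genes")) {
  if (!response %in% colnames(results))
    stop("response column not found: ", response)
  miss <- setdiff(factors, colnames(results))
  if (length(miss))
    stop("factor columns not found: ", paste(miss, collapse = ", "))
  dat <- results[, c(response, factors)]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2L)
      stop("factor with fewer than 2 levels: ", f)
  }
  y <- dat[[response]]
  n <- length(y)
  ss_total <- sum((y - mean(y))^2)
  ss_tol <- 1e-12 * (1 + sum(y^2))  # constant response up to rounding
  contr <- lapply(stats::setNames(factors, factors),
                  function(f) "contr.sum")
  full_fml <- stats::as.formula(
    paste(response, "~", paste(factors, collapse = " + ")))
  full <- stats::lm(full_fml, data = dat, contrasts = contr)
  X <- stats::model.matrix(full)
  if (qr(X)$rank < ncol(X)) {
    al <- stats::alias(full)$Complete
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al), collapse = ", "))
  }
  rss_full <- sum(stats::residuals(full)^2)
  df_resid <- stats::df.residual(full)
  if (df_resid < 1L) stop("no residual degrees of freedom")
  rows <- lapply(factors, function(f) {
    red_fml <- stats::as.formula(
      paste(response, "~", paste(setdiff(factors, f), collapse = " + ")))
    red <- stats::lm(red_fml, data = dat,
                     contrasts = contr[setdiff(factors, f)])
    ss <- sum(stats::residuals(red)^2) - rss_full
    df <- nlevels(dat[[f]]) - 1L
    data.frame(Source = f, SumSq = ss, df = df, MeanSq = ss / df,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (ss_total <= ss_tol) {  # constant response: SS = 0, F = 0, p = 1
    tab$SumSq <- 0
    tab$MeanSq <- 0
    rss_full <- 0
  }
  ms_resid <- rss_full / df_resid
  if (ms_resid > 0) {
    tab$F <- tab$MeanSq / ms_resid
    tab$p <- pf(tab$F, tab$df, df_resid, lower.tail = FALSE)
  } else {
    tab$F <- 0
    tab$p <- 1
  }
  tab$SumSq <- pmax(tab$SumSq, 0)  # guard tiny negatives from rounding
  resid_row <- data.frame(Source = "Residuals", SumSq = rss_full,
                          df = df_resid, MeanSq = ms_resid,
                          F = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE)
  total_row <- data.frame(Source = "Corrected Total",
                          SumSq = ss_total, df = n - 1L,
                          MeanSq = NA_real_, F = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE)
  out <- rbind(tab, resid_row, total_row)
  rownames(out) <- NULL
  out
}
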