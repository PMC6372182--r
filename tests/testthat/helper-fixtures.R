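# Shared fixtures, built in code. The expensive default-fixture pipeline
# run is computed once per test session and reused across files.

suppressMessages(library(SummarizedExperiment))

# small genes x samples CovExperiment with explicit values
makeCE <- function(values, class, series = rep("S1", ncol(values))) {
  values <- matrix(as.numeric(values), nrow(values),
                   dimnames = dimnames(values))
  rn <- rownames(values)
  if (is.null(rn) || anyDuplicated(rn) || !all(nzchar(rn)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  cn <- colnames(values)
  if (is.null(cn) || anyDuplicated(cn) || !all(nzchar(cn)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  CovExperiment(values, class = class, series = series)
}

# pure-noise matrix: 2000 genes x 20 samples, one series
nullCE <- function(seed = 1, n = 20, ngenes = 2000) {
  set.seed(seed)
  m <- matrix(rnorm(ngenes * n, 8, 1), ngenes, n,
              dimnames = list(sprintf("G%04d", seq_len(ngenes)),
                              sprintf("S%02d", seq_len(n))))
  CovExperiment(m, class = rep("?", n))
}

# the default desk-scale study, run once through the full chain
.fixtureCache <- new.env()
defaultFixture <- function() {
  if (is.null(.fixtureCache$run)) {
    sim <- simulateDataset(defaultDesign(seed = 1))
    res <- runPipeline(sim$experiment)
    .fixtureCache$run <- list(sim = sim, res = res)
  }
  .fixtureCache$run
}

# independent brute-force oracles --------------------------------------

# mutual information by direct summation over the joint table
bruteMI <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  total <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      total <- total + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  total
}

# greedy mRMR (MID) coded independently: explicit loops, bruteMI only
bruteMrmr <- function(d, cls, m) {
  genes <- sort(rownames(d))
  d <- d[genes, , drop = FALSE]
  rel <- sapply(genes, function(g) bruteMI(d[g, ], cls))
  sel <- character(0)
  for (step in seq_len(m)) {
    cand <- setdiff(genes, sel)
    best <- NULL; bestv <- -Inf
    for (g in cand) {
      red <- if (length(sel)) mean(sapply(sel, function(s)
        bruteMI(d[g, ], d[s, ]))) else 0
      v <- rel[[g]] - red
      if (v > bestv + 1e-12) { bestv <- v; best <- g }
    }
    sel <- c(sel, best)
  }
  sel
}

# closed-form balanced two-factor main-effects ANOVA sums of squares
balancedAnovaSS <- function(y, f1, f2) {
  gm <- mean(y)
  ss <- function(f) {
    lev <- split(y, f)
    sum(vapply(lev, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  }
  list(ss1 = ss(f1), ss2 = ss(f2),
       total = sum((y - gm)^2))
}
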