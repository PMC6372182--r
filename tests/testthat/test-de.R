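test_that("covMax counts unordered class pairs", {
  expect_identical(covMax(5), 10L)
  expect_identical(covMax(2), 1L)
  expect_identical(covMax(7), choose(7, 2) |> as.integer())
  expect_error(covMax(1), "2 classes")
})

test_that("group-means fit recovers hand-computed means and variances", {
  # 2 classes, values {0,2} and {4,6}: means (1,5), pooled s2 = 2, df = 2
  ce <- makeCE(matrix(c(0, 2, 4, 6), 1, 4), class = c("a", "a", "b", "b"))
  fit <- fitClassMeans(ce)
  expect_equal(unname(fit@means[1, ]), c(1, 5))
  expect_equal(unname(fit@s2), 2)
  expect_equal(fit@df, 2)
  expect_identical(unname(fit@n), c(2L, 2L))

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  ce2 <- makeCE(matrix(c(0, 2, 4, 6)[perm], 1, 4),
                class = c("a", "a", "b", "b")[perm])
  fit2 <- fitClassMeans(ce2)
  expect_equal(fit2@means, fit@means)
  expect_equal(fit2@s2, fit@s2)

  # noise-free planted fixture: fitted means equal planted means
  des <- simulationDesign(nClasses = 5, samplesPerClass = rep(4L, 5),
                          nGenes = 5,
                          plantedMu = matrix(c(0, 3, 0, 0, 0), 1),
                          noiseSd = 1e-9, seriesOffset = 0,
                          seriesScale = 1, baselineMean = 6, seed = 1)
  sim <- simulateDataset(des)
  fit3 <- fitClassMeans(sim$experiment)
  expect_equal(unname(fit3@means[1, des$classNames]),
               6 + c(0, 3, 0, 0, 0), tolerance = 1e-6)
  expect_lt(max(fit3@s2), 1e-12)

  small <- makeCE(matrix(0, 2, 3), class = c("a", "a", "b"))
  expect_error(fitClassMeans(small), "b")
})

test_that("variance moderation limits behave as specified", {
  set.seed(3)
  ce <- makeCE(matrix(rnorm(50 * 12, 8), 50, 12),
               class = rep(c("a", "b"), each = 6))
  fit <- fitClassMeans(ce)
  # d0 = 0: no moderation
  eb0 <- moderateVariances(fit, d0 = 0)
  expect_identical(eb0@s2post, fit@s2)
  # d0 = Inf: complete pooling to the prior
  ebi <- moderateVariances(fit, d0 = Inf)
  expect_true(all(ebi@s2post == ebi@s02))
  # estimated d0: posterior lies between s2 and s02 (monotone shrinkage)
  eb <- moderateVariances(fit)
  lo <- pmin(fit@s2, eb@s02)
  hi <- pmax(fit@s2, eb@s02)
  expect_true(all(eb@s2post >= lo - 1e-12 & eb@s2post <= hi + 1e-12))

  # all variances exactly equal -> zero excess dispersion -> d0 = Inf
  ce2 <- makeCE(matrix(rep(c(0, 2, 4, 1, 3, 5), each = 10), 10, 6),
                class = rep(c("a", "b"), each = 3))
  fit2 <- fitClassMeans(ce2)
  expect_equal(var(fit2@s2), 0)
  eb2 <- moderateVariances(fit2)
  expect_identical(eb2@d0, Inf)
  expect_equal(unname(eb2@s2post), rep(unname(fit2@s2[1]), 10),
               tolerance = 1e-9)

  # degenerate noise-free input
  const <- makeCE(matrix(rep(c(1, 1, 5, 5), each = 3), 3, 4, byrow = FALSE),
                  class = c("a", "a", "b", "b"))
  expect_error(moderateVariances(fitClassMeans(const)), "positive variance")
})

test_that("moment matching recovers a known scaled-F variance prior", {
  set.seed(42)
  d0 <- 4; s02 <- 1; d <- 10; ngene <- 5000
  sigma2 <- s02 * d0 / rchisq(ngene, d0)
  s2 <- sigma2 * rchisq(ngene, d) / d
  fit <- new("GroupFit", means = matrix(0, ngene, 2), s2 = s2, df = d,
             n = c(a = 6L, b = 6L))
  eb <- moderateVariances(fit)
  expect_lt(abs(eb@d0 - d0) / d0, 0.15)
  expect_lt(abs(eb@s02 - s02) / s02, 0.15)
  # matches the reference empirical-Bayes fit
  skip_if_not_installed("limma")
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(eb@d0, ref$df2, tolerance = 1e-6)
  expect_equal(eb@s02, ref$scale, tolerance = 1e-6)
})

test_that("pairwise moderated statistics match the hand formula", {
  ce <- makeCE(matrix(c(0, 2, 4, 6), 1, 4), class = c("a", "a", "b", "b"))
  fit <- fitClassMeans(ce)
  ps <- pairwiseStats(fit, moderateVariances(fit, d0 = 0))
  # t = (1-5)/sqrt(2*(1/2+1/2)) = -2.828..., p from t dist with df = 2
  expect_equal(unname(ps@lfc[1, 1]), -4)
  expect_equal(unname(ps@t[1, 1]), -4 / sqrt(2 * (1 / 2 + 1 / 2)))
  expect_equal(unname(ps@p[1, 1]), 2 * pt(-2 * sqrt(2), df = 2))

  # identical class means: lfc = 0, t = 0, p = 1
  ce2 <- makeCE(matrix(c(1, 3, 1, 3), 1, 4), class = c("a", "a", "b", "b"))
  fit2 <- fitClassMeans(ce2)
  ps2 <- pairwiseStats(fit2, moderateVariances(fit2, d0 = 0))
  expect_equal(unname(ps2@lfc[1, 1]), 0)
  expect_equal(unname(ps2@p[1, 1]), 1)
})

test_that("all pairs are computed with antisymmetric lfc and t", {
  set.seed(11)
  ce <- makeCE(matrix(rnorm(20 * 15, 8), 20, 15),
               class = rep(c("a", "b", "c", "d", "e"), each = 3))
  fit <- fitClassMeans(ce)
  ps <- pairwiseStats(fit, moderateVariances(fit))
  expect_equal(nrow(ps@pairs), covMax(5))
  expect_true(all(ps@p > 0 & ps@p <= 1))
  expect_true(all(sign(ps@t) * sign(ps@lfc) >= 0))
  # swapping a pair's class order negates lfc and t, p unchanged:
  # recompute with reversed mean columns
  i <- 1
  lfc_rev <- fit@means[, ps@pairs[i, 2]] - fit@means[, ps@pairs[i, 1]]
  expect_equal(unname(ps@lfc[, i]), -unname(lfc_rev))
})

test_that("with d0 = 0 and N = 2 p-values equal the classical pooled t-test", {
  set.seed(13)
  ce <- makeCE(matrix(rnorm(30 * 10, 8), 30, 10),
               class = rep(c("a", "b"), each = 5))
  fit <- fitClassMeans(ce)
  ps <- pairwiseStats(fit, moderateVariances(fit, d0 = 0))
  v <- exprsValues(ce)
  for (g in 1:30) {
    tt <- t.test(v[g, 1:5], v[g, 6:10], var.equal = TRUE)
    expect_equal(unname(ps@t[g, 1]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(ps@p[g, 1]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("coverage counts gated pairs and is monotone in both thresholds", {
  fx <- defaultFixture()
  ps <- fx$res$pairwise
  cc <- computeCoverage(ps, 2.5, 0.001)
  expect_true(all(cc >= 0 & cc <= covMax(5)))
  # monotone non-increasing in lfc threshold
  for (thr in c(1, 2, 3, 4)) {
    expect_true(all(computeCoverage(ps, thr + 0.5, 0.001) <=
                      computeCoverage(ps, thr, 0.001)))
  }
  # monotone non-increasing as the p gate tightens
  expect_true(all(computeCoverage(ps, 2.5, 1e-6) <=
                    computeCoverage(ps, 2.5, 0.01)))
  # null gene with all lfc = 0 has coverage 0 at any threshold
  ce0 <- makeCE(matrix(rep(c(1, 3), 5), 1, 10),
                class = rep(c("a", "b"), each = 5))
  fit0 <- fitClassMeans(ce0)
  ps0 <- pairwiseStats(fit0, moderateVariances(fit0, d0 = 0))
  expect_equal(unname(computeCoverage(ps0, 0.5, 0.5)), 0L)
  expect_error(computeCoverage(ps, -1, 0.001), "positive")
  expect_error(computeCoverage(ps, 2.5, 1.5), "pThreshold")
})

test_that("planted coverage is recovered on the default fixture", {
  fx <- defaultFixture()
  truth <- fx$sim$truth
  cc <- computeCoverage(fx$res$pairwise, 2.5, 0.001)
  planted <- truth$gene_id[!truth$is_null]
  agree <- mean(cc[planted] ==
                  truth$expected_cov[match(planted, truth$gene_id)])
  expect_gte(agree, 0.95)
})

test_that("selectDEGs applies the triple rule with deterministic ordering", {
  fx <- defaultFixture()
  ps <- fx$res$pairwise
  degs <- selectDEGs(ps, 2.5, 0.001, 5L)
  expect_true(all(degs$cov >= 5 & degs$cov <= covMax(5)))
  expect_true(all(diff(degs$cov) <= 0))
  # nested as the coverage threshold rises (the ANOVA grid values)
  prev <- selectDEGs(ps, 2.5, 0.001, 2L)$gene_id
  for (ct in 3:5) {
    cur <- selectDEGs(ps, 2.5, 0.001, ct)$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(selectDEGs(ps, 2.5, 0.001, covMax(5) + 1L), "\\[1, 10\\]")

  # single planted gene among nulls, noise-free limit, covThreshold 1
  des <- simulationDesign(nClasses = 5, samplesPerClass = rep(4L, 5),
                          nGenes = 20,
                          plantedMu = matrix(c(0, 3, 0, 0, 0), 1),
                          noiseSd = 1e-4, seriesOffset = 0,
                          seriesScale = 1, baselineMean = 6, seed = 5)
  sim <- simulateDataset(des)
  fit <- fitClassMeans(sim$experiment)
  ps1 <- pairwiseStats(fit, moderateVariances(fit))
  degs1 <- selectDEGs(ps1, 2.5, 0.001, 1L)
  expect_identical(degs1$gene_id, "G0001")
  expect_equal(degs1$cov, 4L)
  # summaries averaged over covered pairs only: mean |lfc| of the 4
  # covered pairs is 3
  expect_equal(degs1$mean_abs_lfc, 3, tolerance = 1e-3)
})
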