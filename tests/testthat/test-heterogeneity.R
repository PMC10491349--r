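# Radial outliers, PRESSO-style testing, ratio clustering.

test_that("radial first-order Q contributions sum to Cochran's Q exactly", {
  h <- makeHarmonized(20, slope = 0.4, noise = 0.05, seed = 14)
  rep1 <- radialOutliers(h, weights = "first")
  ivw <- mrIVW(h, "fe")
  q <- cochranQ(h, ivw@beta)
  expect_equal(sum(rep1@perSnp$q_contribution), q$Q, tolerance = 1e-10)
  expect_equal(rep1@estimateOriginal@beta, mrIVW(h, "mre")@beta,
               tolerance = 1e-12)
})

test_that("homogeneous noiseless data flag nothing and keep the estimate", {
  h <- makeHarmonized(10, slope = 0.4, noise = 0, seed = 15)
  r <- radialOutliers(h)
  expect_false(any(r@perSnp$flagged))
  expect_identical(r@estimateCorrected@beta, r@estimateOriginal@beta)

  p <- mrPresso(h, nSim = 200, seed = 3)
  expect_false(any(p@perSnp$flagged))
  # degenerate path: no outliers means no distortion test
  expect_true(is.na(p@distortionPval))
  expect_identical(p@estimateCorrected@beta, p@estimateOriginal@beta)
})

test_that("planted outliers are flagged and correction tightens the CI", {
  sim <- generateDataset(mediationScenario("outlier_default", seed = 77))
  h <- harmonizeTraits(sim$exposure, sim$outcome)
  out <- sim$truth@outlierIds

  r <- radialOutliers(h)
  expect_gte(sum(out %in% r@perSnp$snp_id[r@perSnp$flagged]), 2)
  p <- mrPresso(h, nSim = 1000, seed = 77)
  expect_gte(sum(out %in% p@perSnp$snp_id[p@perSnp$flagged]), 2)
  expect_lt(p@globalPval, 0.05)
  expect_false(is.na(p@distortionPval))

  # flagged SNPs carry the largest heterogeneity: corrected SE shrinks
  expect_lte(r@estimateCorrected@se, r@estimateOriginal@se)
})

test_that("presso guards its preconditions", {
  h <- makeHarmonized(10, noise = 0.02, seed = 16)
  expect_error(mrPresso(h, nSim = 50), "insufficient simulations")
  expect_error(mrPresso(makeHarmonized(3), nSim = 200), ">= 4")
  expect_error(radialOutliers(makeHarmonized(2)), ">= 3")
})

test_that("presso is deterministic given a seed", {
  h <- makeHarmonized(15, noise = 0.05, seed = 17)
  a <- mrPresso(h, nSim = 300, seed = 5)
  b <- mrPresso(h, nSim = 300, seed = 5)
  expect_identical(a@globalPval, b@globalPval)
  expect_identical(a@perSnp$outlier_pval, b@perSnp$outlier_pval)
})

test_that("a single shared mechanism clusters as K = 1, all assigned", {
  set.seed(18)
  L <- 15
  bx <- rnorm(L, 0.3, 0.05)
  by <- 0.4 * bx + rnorm(L, 0, 0.005)
  h <- HarmonizedMRData(sprintf("rs%03d", 1:L), bx, rep(0.005, L), by,
                        rep(0.005, L))
  ca <- clusterRatios(h, maxK = 4, seed = 1)
  expect_equal(ca@K, 1L)
  expect_true(all(ca@assignments$label == "cluster_1"))
  expect_true(all(ca@assignments$probability >= 0.9))
})

test_that("pure noise around zero lands in the null cluster", {
  set.seed(19)
  L <- 12
  bx <- rnorm(L, 0.3, 0.05)
  by <- rnorm(L, 0, 0.005)
  h <- HarmonizedMRData(sprintf("rs%03d", 1:L), bx, rep(0.005, L), by,
                        rep(0.005, L))
  ca <- clusterRatios(h, maxK = 4, seed = 2)
  expect_equal(ca@K, 0L)
  expect_true(all(ca@assignments$label == "null"))
})

test_that("two planted mechanisms are recovered with high confidence", {
  sim <- generateDataset(mediationScenario("clustered_dense_area", seed = 21))
  h <- harmonizeTraits(sim$exposure, sim$outcome)
  ca <- clusterRatios(h, maxK = 5, seed = 21)
  expect_equal(ca@K, 2L)
  truthLab <- setNames(sim$truth@clusterLabels, sim$truth@snpIds)
  expect_gte(clusterAccuracy(ca@assignments, truthLab), 0.9)
  # probabilities sum to one per SNP
  expect_equal(unname(rowSums(ca@probabilities)), rep(1, nSnps(h)),
               tolerance = 1e-8)
})

test_that("clustering is deterministic given seed, order-insensitive", {
  sim <- generateDataset(mediationScenario("clustered_dense_area", seed = 22))
  h <- harmonizeTraits(sim$exposure, sim$outcome)
  a <- clusterRatios(h, seed = 4)
  b <- clusterRatios(h, seed = 4)
  expect_identical(a@assignments, b@assignments)
  d <- associations(sim$exposure)
  set.seed(1)
  exShuf <- GwasSummaryStats("exposure", "continuous", d[sample(nrow(d)), ])
  hShuf <- harmonizeTraits(exShuf, sim$outcome)
  c2 <- clusterRatios(hShuf, seed = 4)
  expect_identical(a@assignments, c2@assignments)
})
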