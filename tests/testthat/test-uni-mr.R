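# Univariable estimators: Wald ratios, IVW, Egger, weighted median,
# Cochran's Q, mean F, Steiger filtering.

test_that("Wald ratios equal element-wise division with first-order SE", {
  h <- makeHarmonized(21, slope = 0.5, noise = 0.01, seed = 7)
  wr <- waldRatios(h)
  expect_equal(wr$ratio, betaOutcome(h) / betaExposure(h)[, 1],
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(wr$se, seOutcome(h) / abs(betaExposure(h)[, 1]),
               tolerance = 1e-15, ignore_attr = TRUE)

  # arithmetic example and the zero-outcome case
  h2 <- HarmonizedMRData(c("rs1", "rs2"), c(0.2, 0.1), c(0.01, 0.01),
                         c(0.1, 0), c(0.02, 0.02))
  wr2 <- waldRatios(h2)
  expect_equal(wr2$ratio, c(0.5, 0))
  expect_equal(wr2$se[1], 0.1)

  # SNPs with zero exposure effect are excluded, all-zero errors
  h3 <- HarmonizedMRData(c("rs1", "rs2"), c(0, 0.1), c(0.01, 0.01),
                         c(0.1, 0.05), c(0.02, 0.02))
  expect_message(wr3 <- waldRatios(h3), "zero exposure")
  expect_equal(nrow(wr3), 1)
  h4 <- HarmonizedMRData("rs1", 0, 0.01, 0.1, 0.02)
  expect_error(waldRatios(h4), "zero")

  # second-order SE is never smaller than first-order
  wrs <- waldRatios(h, seOrder = "second")
  expect_true(all(wrs$se >= wr$se))
})

test_that("IVW equals the closed-form weighted regression through origin", {
  h <- makeHarmonized(20, slope = 0.4, noise = 0.03, seed = 11)
  bx <- betaExposure(h)[, 1]; by <- betaOutcome(h); sy <- seOutcome(h)
  w <- 1 / sy^2
  slope <- sum(w * bx * by) / sum(w * bx^2)

  fe <- mrIVW(h, "fe")
  expect_equal(fe@beta, slope, tolerance = 1e-10)
  expect_equal(fe@se, sqrt(1 / sum(w * bx^2)), tolerance = 1e-10)

  mre <- mrIVW(h, "mre")
  expect_equal(mre@beta, slope, tolerance = 1e-10)
  expect_equal(mre@se, fe@se * max(1, sqrt(fe@Q / (20 - 1))),
               tolerance = 1e-10)
  expect_gte(mre@se, fe@se)
})

test_that("IVW on a single SNP reduces to its Wald ratio", {
  h <- HarmonizedMRData("rs1", 0.2, 0.01, 0.1, 0.02)
  est <- mrIVW(h, "fe")
  expect_equal(est@beta, 0.5)
  expect_equal(est@se, 0.1)
  est2 <- mrIVW(h, "mre")
  expect_equal(est2@se, 0.1)  # no inflation possible at L = 1

  # all outcome effects zero gives a zero estimate
  hz <- makeHarmonized(5, slope = 0, noise = 0, seed = 3)
  expect_equal(mrIVW(hz)@beta, 0)
})

test_that("Egger recovers an exact affine relationship and matches WLS", {
  set.seed(21)
  bx <- abs(rnorm(10, 0.1, 0.03))
  by <- 0.01 + 0.4 * bx
  h <- HarmonizedMRData(sprintf("rs%02d", 1:10), bx, rep(0.005, 10), by,
                        rep(0.02, 10))
  e <- mrEgger(h)
  expect_equal(e@intercept, 0.01, tolerance = 1e-10)
  expect_equal(e@beta, 0.4, tolerance = 1e-10)
  expect_equal(e@Q, 0, tolerance = 1e-16)

  # independent WLS oracle on noisy data
  h2 <- makeHarmonized(20, slope = 0.4, noise = 0.05, seed = 22)
  bx2 <- betaExposure(h2)[, 1]; by2 <- betaOutcome(h2); sy2 <- seOutcome(h2)
  flip <- sign(bx2)
  fit <- lm(I(by2 * flip) ~ I(bx2 * flip), weights = 1 / sy2^2)
  e2 <- mrEgger(h2)
  expect_equal(e2@beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e2@intercept, unname(coef(fit)[1]), tolerance = 1e-10)

  expect_error(mrEgger(makeHarmonized(2)), "insufficient")
})

test_that("Egger slope equals IVW slope at zero intercept with equal weights", {
  # exact: both are WLS on the same design when the fitted intercept is 0
  set.seed(23)
  bx <- abs(rnorm(15, 0.1, 0.02))
  by <- 0.4 * bx
  h <- HarmonizedMRData(sprintf("rs%02d", 1:15), bx, rep(0.005, 15), by,
                        rep(0.02, 15))
  expect_equal(mrEgger(h)@beta, mrIVW(h, "fe")@beta, tolerance = 1e-10)
})

test_that("weighted median interpolates the ratio at half the weight", {
  # equal weights, ratios {0.1, 0.2, 0.9}: midpoints 1/6, 1/2, 5/6 put
  # the estimate exactly on the middle ratio
  h <- HarmonizedMRData(c("rs1", "rs2", "rs3"), c(1, 1, 1), rep(1e-6, 3),
                        c(0.1, 0.2, 0.9), rep(0.02, 3))
  wm <- mrWeightedMedian(h, nBoot = 50, seed = 1)
  expect_equal(wm@beta, 0.2, tolerance = 1e-12)

  # constancy: identical ratios give that ratio whatever the weights
  h2 <- HarmonizedMRData(c("rs1", "rs2", "rs3"), c(0.1, 0.2, 0.4),
                         c(0.01, 0.01, 0.01), c(0.05, 0.1, 0.2),
                         c(0.01, 0.03, 0.09))
  expect_equal(mrWeightedMedian(h2, nBoot = 50, seed = 1)@beta, 0.5,
               tolerance = 1e-12)

  expect_error(mrWeightedMedian(makeHarmonized(2)), "insufficient")

  # bootstrap SE is reproducible under a fixed seed
  h3 <- makeHarmonized(10, noise = 0.02, seed = 30)
  a <- mrWeightedMedian(h3, nBoot = 200, seed = 9)
  b <- mrWeightedMedian(h3, nBoot = 200, seed = 9)
  expect_identical(a@se, b@se)
})

test_that("Cochran's Q matches hand arithmetic and is zero when homogeneous", {
  # two SNPs, ratios 0 and 1, unit weights, beta_hat = 0.5 -> Q = 0.5
  h <- HarmonizedMRData(c("rs1", "rs2"), c(1, 1), c(0.01, 0.01), c(0, 1),
                        c(1, 1))
  q <- cochranQ(h, 0.5)
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1)

  hom <- makeHarmonized(8, slope = 0.3, noise = 0, seed = 4)
  qh <- cochranQ(hom, 0.3)
  expect_equal(qh$Q, 0, tolerance = 1e-16)
  expect_equal(qh$pval, 1)

  expect_error(cochranQ(HarmonizedMRData("rs1", 1, 1, 1, 1), 0.5), ">= 2")
})

test_that("mean F statistic averages squared per-SNP z scores", {
  h <- HarmonizedMRData("rs1", 0.1, 0.02, 0, 0.02)
  expect_equal(meanFStatistic(h), 25)
  hz <- HarmonizedMRData(c("rs1", "rs2"), c(0, 0), c(0.01, 0.01),
                         c(0, 0), c(0.02, 0.02))
  expect_equal(meanFStatistic(hz), 0)
})

test_that("Steiger filtering keeps correct-direction and boundary SNPs", {
  # strong on the exposure: retained
  h <- HarmonizedMRData(c("rs1", "rs2", "rs3"),
                        c(0.10, 0.10, 0.004), rep(0.004, 3),
                        c(0.02, 0.02, 0.10), rep(0.004, 3),
                        nX = 50000, nY = 50000)
  sf <- steigerFilter(h)
  expect_true(all(c("rs1", "rs2") %in% sf$result@retainedSnps))
  # rs3 explains far more outcome variance: removed
  expect_false("rs3" %in% sf$result@retainedSnps)
  expect_equal(nSnps(sf$data), 2)

  # equal r-squared cannot be rejected: retained
  he <- HarmonizedMRData("rs1", 0.1, 0.004, 0.1, 0.004,
                         nX = 50000, nY = 50000)
  expect_equal(steigerFilter(he)$result@retainedSnps, "rs1")

  hn <- HarmonizedMRData("rs1", 0.1, 0.004, 0.1, 0.004)
  expect_error(steigerFilter(hn), "sample sizes")
})

test_that("estimators are invariant to SNP order and allele recoding", {
  sim <- generateDataset(simulationConfig(seed = 31, nSnps = 25,
                                          gammaSD = 0.1, betaDirect = 0.3,
                                          outcomeType = "continuous"))
  h1 <- harmonizeTraits(sim$exposure, sim$outcome)

  # permute input record order
  shuf <- function(s) {
    d <- associations(s)
    GwasSummaryStats(traitName(s), traitType(s),
                     d[sample(nrow(d)), , drop = FALSE])
  }
  set.seed(5)
  h2 <- harmonizeTraits(shuf(sim$exposure), shuf(sim$outcome))
  # recode random subsets of both traits
  set.seed(6)
  h3 <- harmonizeTraits(recodeAlleles(sim$exposure, sample(25, 12)),
                        recodeAlleles(sim$outcome, sample(25, 9)))
  for (h in list(h2, h3)) {
    expect_equal(mrIVW(h)@beta, mrIVW(h1)@beta, tolerance = 1e-14)
    expect_equal(mrEgger(h)@beta, mrEgger(h1)@beta, tolerance = 1e-14)
    expect_equal(mrEgger(h)@intercept, mrEgger(h1)@intercept,
                 tolerance = 1e-14)
    expect_identical(mrWeightedMedian(h, nBoot = 100, seed = 2)@se,
                     mrWeightedMedian(h1, nBoot = 100, seed = 2)@se)
  }
})

test_that("MRE coverage is near nominal without pleiotropy", {
  reps <- 200
  cover <- vapply(seq_len(reps), function(r) {
    cfg <- simulationConfig(seed = 40000 + r, nSnps = 30, gammaSD = 0.1,
                            betaDirect = 0.25, outcomeType = "continuous")
    sim <- generateDataset(cfg)
    est <- mrIVW(harmonizeTraits(sim$exposure, sim$outcome), "mre")
    est@ciLow <= 0.25 && 0.25 <= est@ciHigh
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})
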