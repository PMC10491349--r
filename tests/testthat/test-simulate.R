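# The summary-statistic simulator: determinism, noise model, truth.

test_that("identical configs give byte-identical datasets", {
  cfg <- mediationScenario("dense_area_default", seed = 5)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(associations(a$exposure), associations(b$exposure))
  expect_identical(associations(a$outcome), associations(b$outcome))
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  writeDataset(a, dirA); writeDataset(b, dirB)
  for (f in list.files(dirA))
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)))
  # a different seed changes the draws
  c <- generateDataset(mediationScenario("dense_area_default", seed = 6))
  expect_false(identical(associations(a$exposure)$beta,
                         associations(c$exposure)$beta))
})

test_that("with all noise off the mediator/exposure ratio is exactly alpha", {
  cfg <- simulationConfig(seed = 2, nSnps = 20, gammaSD = 0.1, alpha = -0.3,
                          nExposure = 1e12, nMediator = 1e12, nOutcome = 1e12)
  sim <- generateDataset(cfg)
  h <- harmonizeTraits(sim$exposure, sim$mediator)
  expect_equal(betaOutcome(h) / betaExposure(h)[, 1],
               rep(-0.3, 20), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("empirical SE of simulated betas matches the analytic SE", {
  # single fixed MAF so every replicate shares one analytic SE
  reps <- 1500
  betas <- vapply(seq_len(reps), function(r) {
    cfg <- simulationConfig(seed = r, nSnps = 1, mafRange = c(0.3, 0.3),
                            gammaSD = 0, nExposure = 40000)
    associations(generateDataset(cfg)$exposure)$beta
  }, numeric(1))
  analytic <- 1 / sqrt(2 * 0.3 * 0.7 * 40000)
  expect_lt(abs(sd(betas) - analytic) / analytic, 0.05)
})

test_that("binary outcomes use the case-fraction-adjusted SE", {
  cfg <- simulationConfig(seed = 3, nSnps = 4, mafRange = c(0.2, 0.2),
                          nOutcome = 10000, outcomeType = "binary",
                          caseFraction = 0.3)
  sim <- generateDataset(cfg)
  expect_equal(associations(sim$outcome)$se,
               rep(1 / sqrt(2 * 0.2 * 0.8 * 10000 * 0.3 * 0.7), 4))
  expect_identical(traitType(sim$outcome), "binary")
})

test_that("truth slots are algebraically consistent", {
  cfg <- mediationScenario("dense_area_default")
  sim <- generateDataset(cfg)
  t <- sim$truth
  expect_identical(t@totalEffect, t@betaDirect + t@alpha * t@betaMed)
  expect_identical(t@proportionMediated,
                   t@alpha * t@betaMed / t@totalEffect)
  expect_equal(t@totalEffect, -0.41, tolerance = 1e-12)
  expect_equal(t@proportionMediated, 0.56, tolerance = 1e-12)
})

test_that("scenario presets encode their advertised structure", {
  expect_equal(mediationScenario("null_mediation")@alpha, 0)
  t0 <- generateDataset(mediationScenario("null_mediation"))$truth
  expect_equal(t0@proportionMediated, 0)

  cl <- mediationScenario("clustered_dense_area")
  expect_length(cl@clusterSpec, 2)
  slopes <- vapply(cl@clusterSpec, `[`, numeric(1), 2)
  expect_true(any(slopes > 0) && any(slopes < 0))
  tcl <- generateDataset(cl)$truth
  expect_equal(sum(tcl@clusterLabels == "cluster_1"), 10)
  expect_equal(sum(tcl@clusterLabels == "cluster_2"), 10)
  expect_equal(sum(tcl@clusterLabels == "null"), 5)

  out <- generateDataset(mediationScenario("outlier_default"))$truth
  expect_length(out@outlierIds, 3)

  expect_error(mediationScenario("nope"), "dense_area_default")
})

test_that("homogeneous simulations give chi-squared Cochran's Q", {
  reps <- 500; L <- 15
  q <- vapply(seq_len(reps), function(r) {
    cfg <- simulationConfig(seed = 20000 + r, nSnps = L, gammaSD = 0.1,
                            nExposure = 5e5, betaDirect = 0.2,
                            outcomeType = "continuous")
    sim <- generateDataset(cfg)
    h <- harmonizeTraits(sim$exposure, sim$outcome)
    mrIVW(h, "fe")@Q
  }, numeric(1))
  expect_lt(abs(mean(q) - (L - 1)), 3 * sqrt(2 * (L - 1) / reps))
})
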