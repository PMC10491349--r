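# Multivariable MR: direct effects, conditional F, Q_A.

makeMVHarmonized <- function(L = 30, b = c(0.3, -0.2), noise = 0, seed = 8,
                             sx = 0.005, sy = 0.02) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(L, 0, 0.1), x2 = rnorm(L, 0, 0.1))
  y <- drop(X %*% b) + rnorm(L, 0, noise)
  HarmonizedMRData(sprintf("rs%03d", seq_len(L)), X,
                   matrix(sx, L, 2), y, rep(sy, L), nX = 1e5, nY = 1e5)
}

test_that("noiseless linear data are recovered exactly and Q_A is zero", {
  h <- makeMVHarmonized(noise = 0)
  fit <- suppressWarnings(mvmrIVW(h))
  expect_equal(unname(mrBeta(fit)), c(0.3, -0.2), tolerance = 1e-12)
  expect_equal(fit@QA, 0, tolerance = 1e-14)
  expect_equal(fit@QAdf, 30 - 2)
})

test_that("a negligible second exposure reproduces univariable IVW", {
  set.seed(9)
  L <- 25
  x1 <- rnorm(L, 0, 0.1)
  x2 <- rnorm(L, 0, 1e-8)           # all zeros except negligible
  y <- 0.4 * x1                     # no residual for x2 to absorb
  h2 <- HarmonizedMRData(sprintf("rs%03d", 1:L), cbind(a = x1, b = x2),
                         matrix(0.005, L, 2), y, rep(0.02, L),
                         nX = 1e5, nY = 1e5)
  h1 <- HarmonizedMRData(sprintf("rs%03d", 1:L), x1, rep(0.005, L), y,
                         rep(0.02, L), nX = 1e5, nY = 1e5)
  fit <- suppressWarnings(mvmrIVW(h2))
  expect_equal(unname(mrBeta(fit)[1]), mrIVW(h1, "fe")@beta,
               tolerance = 1e-10)

  # exact collinearity is a hard error
  hc <- HarmonizedMRData(sprintf("rs%03d", 1:L), cbind(x1, x1),
                         matrix(0.005, L, 2), y, rep(0.02, L))
  expect_error(mvmrIVW(hc), "collinear")
})

test_that("estimates are invariant to exposure column order", {
  h <- makeMVHarmonized(noise = 0.02, seed = 10)
  fit12 <- suppressWarnings(mvmrIVW(h))
  hswap <- HarmonizedMRData(snpIds(h), betaExposure(h)[, 2:1],
                            seExposure(h)[, 2:1], betaOutcome(h),
                            seOutcome(h), nX = 1e5, nY = 1e5)
  fit21 <- suppressWarnings(mvmrIVW(hswap))
  expect_equal(unname(mrBeta(fit21)), unname(mrBeta(fit12)[2:1]),
               tolerance = 1e-12)
  expect_equal(fit21@QA, fit12@QA, tolerance = 1e-12)
})

test_that("conditional F vanishes under collinearity, matches strength when orthogonal", {
  set.seed(12)
  L <- 40
  x1 <- rnorm(L, 0, 0.1)
  # identical columns: conditional F ~ 0
  h <- HarmonizedMRData(sprintf("rs%03d", 1:L), cbind(x1, x1 + rnorm(L, 0, 1e-10)),
                        matrix(0.005, L, 2), 0.3 * x1, rep(0.02, L))
  expect_lt(conditionalF(h, 1), 1e-10)

  # orthogonal strong instruments: conditional F near the univariable mean F
  reps <- 50
  ratio <- vapply(seq_len(reps), function(r) {
    set.seed(100 + r)
    X <- cbind(c(rnorm(20, 0, 0.1), rep(0, 20)),
               c(rep(0, 20), rnorm(20, 0, 0.1)))
    X <- X + rnorm(80, 0, 0.005)
    hh <- HarmonizedMRData(sprintf("rs%03d", 1:40), X, matrix(0.005, 40, 2),
                           rnorm(40, 0, 0.02), rep(0.02, 40))
    h1 <- HarmonizedMRData(sprintf("rs%03d", 1:40), X[, 1], rep(0.005, 40),
                           rnorm(40, 0, 0.02), rep(0.02, 40))
    conditionalF(hh, 1) / meanFStatistic(h1)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.25)
})

test_that("Q_A matches its formula and detects planted pleiotropy", {
  h <- makeMVHarmonized(noise = 0.02, seed = 13)
  b <- c(0.25, -0.15)
  qa <- mvmrQA(h, b)
  expect_equal(qa$Q, sum((betaOutcome(h) -
                          drop(betaExposure(h) %*% b))^2 / seOutcome(h)^2),
               tolerance = 1e-12)

  # planted pleiotropy in 20% of SNPs inflates Q_A
  reps <- 50
  rej <- vapply(seq_len(reps), function(r) {
    set.seed(200 + r)
    L <- 30
    X <- matrix(rnorm(2 * L, 0, 0.1), L, 2)
    y <- drop(X %*% c(0.3, -0.2)) + rnorm(L, 0, 0.02)
    idx <- sample(L, 6)
    y[idx] <- y[idx] + 0.1
    hh <- HarmonizedMRData(sprintf("rs%03d", 1:L), X, matrix(0.005, L, 2),
                           y, rep(0.02, L))
    suppressWarnings(mvmrIVW(hh))@QApval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("mediation-scenario MVMR recovers the direct effects", {
  reps <- 100
  est <- t(vapply(seq_len(reps), function(r) {
    sim <- generateDataset(mediationScenario("dense_area_default",
                                             seed = 50000 + r))
    h <- harmonizeTraits(list(sim$exposure, sim$mediator), sim$outcome)
    unname(mrBeta(suppressWarnings(mvmrIVW(h))))
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - (-0.1804)), 0.02)
  expect_lt(abs(mean(est[, 2]) - 0.41), 0.02)
})
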