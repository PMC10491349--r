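## Per-SNP heterogeneity decomposition: radial outlier detection and
## PRESSO-style global / outlier / distortion testing.

#' Radial outlier detection
#'
#' Radial reparameterization of the IVW regression: ratio_j * sqrt(w_j) is
#' regressed on sqrt(w_j) through the origin, making each SNP's
#' contribution Q_j = w_j (ratio_j - beta_hat)^2 to the heterogeneity
#' statistic explicit. With first-order weights w_j = beta_Xj^2 / se_Yj^2
#' the Q_j sum exactly to Cochran's Q. Modified second-order weights
#' w_j = (se_Yj^2/beta_Xj^2 + beta_hat^2 se_Xj^2/beta_Xj^2)^(-1) are
#' iterated with the estimate until convergence (|change| < 1e-8, at most
#' 100 iterations). A SNP is flagged when the upper tail of chi-squared(1)
#' at Q_j falls below \code{alpha} (default Bonferroni, 0.05 / L). The
#' outlier-corrected estimate is IVW (multiplicative random effects) on
#' the unflagged SNPs.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least three SNPs.
#' @param alpha per-SNP significance level, or \code{"bonferroni"}
#'   (default) for 0.05 / L.
#' @param weights \code{"modified_second"} (default), \code{"second"} or
#'   \code{"first"} order radial weights.
#' @return an \linkS4class{OutlierReport}.
#' @export
radialOutliers <- function(data, alpha = "bonferroni",
                           weights = c("modified_second", "first", "second")) {
  checkUnivariable(data)
  weights <- match.arg(weights)
  bx <- data@betaX[, 1]; by <- data@betaY
  sx <- data@seX[, 1]; sy <- data@seY
  L <- length(bx)
  if (L < 3L) stop("radial outlier detection needs >= 3 SNPs")
  if (identical(alpha, "bonferroni")) alpha <- 0.05 / L
  ratio <- by / bx

  radialFit <- function(w) sum(w * ratio) / sum(w)
  w1 <- bx^2 / sy^2
  beta <- radialFit(w1)
  if (weights == "first") {
    w <- w1
  } else {
    ## second-order weights depend on the estimate; iterate to a fixed
    ## point (for plain "second" a single pass at the first-order fit)
    iter <- 0L
    repeat {
      w <- 1 / (sy^2 / bx^2 + beta^2 * sx^2 / bx^2)
      newBeta <- radialFit(w)
      iter <- iter + 1L
      if (weights == "second") { beta <- newBeta; break }
      if (abs(newBeta - beta) < 1e-8) { beta <- newBeta; break }
      beta <- newBeta
      if (iter >= 100L)
        stop("radial estimate did not converge after 100 iterations; ",
             "last estimates: ", paste(signif(c(beta, newBeta), 10),
                                       collapse = " -> "))
    }
  }
  Qj <- w * (ratio - beta)^2
  pj <- stats::pchisq(Qj, df = 1, lower.tail = FALSE)
  flagged <- pj < alpha
  perSnp <- data.frame(snp_id = data@snpIds, ratio = ratio, weight = w,
                       q_contribution = Qj, outlier_pval = pj,
                       flagged = flagged, stringsAsFactors = FALSE)
  original <- mrIVW(data, mode = "mre")
  corrected <- if (any(flagged) && sum(!flagged) >= 1)
    mrIVW(subsetSnps(data, data@snpIds[!flagged]), mode = "mre")
  else original
  new("OutlierReport", method = "radial", perSnp = perSnp,
      globalPval = NA_real_, distortionPval = NA_real_,
      estimateOriginal = original, estimateCorrected = corrected)
}

## Leave-one-out IVW slopes for every SNP, from the weighted totals.
looSlopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' PRESSO-style pleiotropy testing
#'
#' Global test: the observed residual sum of squares (each SNP's outcome
#' effect against its leave-one-out IVW prediction, standardized by its
#' SE) is compared with \code{nSim} parametric simulations drawn under
#' the fitted model with each SNP's reported SEs; the p-value is
#' empirical. Outlier test: each SNP's observed standardized squared
#' residual is compared with its own simulated null, Bonferroni-corrected
#' at \code{outlierAlpha}. Distortion test: the shift between the original
#' and the outlier-removed IVW estimate is compared with a null built by
#' removing random SNP subsets of the same size. The corrected estimate is
#' IVW (multiplicative random effects) on the non-outliers. All
#' randomness is governed by \code{seed}.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least four SNPs.
#' @param nSim number of parametric simulations (>= 100; default 1000).
#' @param outlierAlpha familywise level of the per-SNP outlier test
#'   (default 0.05).
#' @param seed RNG seed.
#' @return an \linkS4class{OutlierReport}.
#' @export
mrPresso <- function(data, nSim = 1000, outlierAlpha = 0.05, seed = 1) {
  checkUnivariable(data)
  if (nSim < 100) stop("insufficient simulations (need nSim >= 100)")
  bx <- data@betaX[, 1]; by <- data@betaY
  sx <- data@seX[, 1]; sy <- data@seY
  L <- length(bx)
  if (L < 4L) stop("PRESSO testing needs >= 4 SNPs")
  ## canonical orientation so simulation draws do not depend on coding
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  w <- 1 / sy^2

  loo <- looSlopes(bx, by, w)
  obsRes2 <- ((by - loo * bx) / sy)^2
  obsRSS <- sum(obsRes2)

  simRes2 <- withSeed(deriveSeed(seed, 1L), {
    m <- matrix(NA_real_, nSim, L)
    for (s in seq_len(nSim)) {
      bxs <- stats::rnorm(L, bx, sx)
      bys <- stats::rnorm(L, loo * bx, sy)
      loos <- looSlopes(bxs, bys, w)
      m[s, ] <- ((bys - loos * bxs) / sy)^2
    }
    m
  })
  globalPval <- (sum(rowSums(simRes2) >= obsRSS) + 1) / (nSim + 1)
  outlierPval <- (colSums(simRes2 >= rep(obsRes2, each = nSim)) + 1) /
    (nSim + 1)
  flagged <- outlierPval * L < outlierAlpha

  original <- mrIVW(data, mode = "mre")
  if (any(flagged) && sum(!flagged) >= 1) {
    corrected <- mrIVW(subsetSnps(data, data@snpIds[!flagged]), mode = "mre")
    nOut <- sum(flagged)
    dObs <- corrected@beta - original@beta
    distortionPval <- if (nOut < L) {
      dNull <- withSeed(deriveSeed(seed, 2L), {
        vapply(seq_len(nSim), function(s) {
          drop_idx <- sample.int(L, nOut)
          wk <- w[-drop_idx]; bxk <- bx[-drop_idx]; byk <- by[-drop_idx]
          sum(wk * bxk * byk) / sum(wk * bxk^2) - original@beta
        }, numeric(1))
      })
      (sum(abs(dNull) >= abs(dObs)) + 1) / (nSim + 1)
    } else NA_real_
  } else {
    corrected <- original
    distortionPval <- NA_real_
  }
  perSnp <- data.frame(snp_id = data@snpIds, ratio = by / bx,
                       weight = bx^2 / sy^2, q_contribution = obsRes2,
                       outlier_pval = outlierPval, flagged = flagged,
                       stringsAsFactors = FALSE)
  new("OutlierReport", method = "presso", perSnp = perSnp,
      globalPval = globalPval, distortionPval = distortionPval,
      estimateOriginal = original, estimateCorrected = corrected)
}
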