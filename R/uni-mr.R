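## Univariable two-sample MR estimators and diagnostics.

checkUnivariable <- function(data) {
  stopifnot(is(data, "HarmonizedMRData"))
  if (ncol(data@betaX) != 1L)
    stop("univariable MR requires exactly one exposure")
}

#' Per-SNP Wald ratio estimates
#'
#' Computes the per-variant causal estimate (outcome effect divided by
#' exposure effect). The default standard error is the first-order delta
#' approximation se_Y / |beta_X|; the second-order form additionally
#' propagates the exposure-side uncertainty. Variants with a zero exposure
#' effect are excluded with a logged reason.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure.
#' @param seOrder \code{"first"} (default) or \code{"second"} order delta
#'   standard errors.
#' @return data.frame with columns \code{snp_id}, \code{ratio}, \code{se}.
#' @export
waldRatios <- function(data, seOrder = c("first", "second")) {
  checkUnivariable(data)
  seOrder <- match.arg(seOrder)
  bx <- data@betaX[, 1]; by <- data@betaY
  sx <- data@seX[, 1]; sy <- data@seY
  keep <- bx != 0
  if (!any(keep)) stop("all exposure effects are zero")
  if (any(!keep))
    message(sum(!keep), " SNP(s) with zero exposure effect excluded")
  bx <- bx[keep]; by <- by[keep]; sx <- sx[keep]; sy <- sy[keep]
  ratio <- by / bx
  se <- if (seOrder == "first") sy / abs(bx)
        else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  data.frame(snp_id = data@snpIds[keep], ratio = ratio, se = se,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted least-squares slope of the outcome effects on the exposure
#' effects through the origin, with weights 1/se_Y^2 — equivalently the
#' inverse-variance weighted average of the per-SNP Wald ratios. The
#' fixed-effect standard error is the analytic WLS one; the multiplicative
#' random-effects (MRE) flavour scales it by max(1, sqrt(Q / (L - 1))),
#' where Q is Cochran's heterogeneity statistic.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure.
#' @param mode \code{"mre"} (multiplicative random effects, default) or
#'   \code{"fe"} (fixed effect).
#' @return an \linkS4class{MREstimate}.
#' @export
mrIVW <- function(data, mode = c("mre", "fe")) {
  checkUnivariable(data)
  mode <- match.arg(mode)
  bx <- data@betaX[, 1]; by <- data@betaY; sy <- data@seY
  L <- length(bx)
  if (L == 0L) stop("no SNPs available")
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se <- sqrt(1 / sxx)
  Q <- sum(w * (by - beta * bx)^2)
  Qdf <- L - 1
  Qpval <- if (Qdf >= 1) stats::pchisq(Q, Qdf, lower.tail = FALSE) else NA_real_
  if (mode == "mre" && Qdf >= 1) se <- se * max(1, sqrt(Q / Qdf))
  ci <- waldCI(beta, se)
  new("MREstimate", method = paste0("ivw_", mode), beta = beta, se = se,
      ciLow = ci[1], ciHigh = ci[2], pval = zPval(beta, se),
      nSnps = L, Q = Q, Qdf = as.numeric(Qdf), Qpval = Qpval,
      meanF = meanFStatistic(data))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept (weights 1/se_Y^2). Inputs are first oriented so that all
#' exposure effects are non-negative (outcome effects flipped along),
#' which the intercept needs to be interpretable as the average
#' directional pleiotropic effect. Both standard errors are scaled by
#' max(1, sqrt(Q_egger / (L - 2))).
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least three SNPs.
#' @return an \linkS4class{MREstimate} with intercept slots populated.
#' @export
mrEgger <- function(data) {
  checkUnivariable(data)
  bx <- data@betaX[, 1]; by <- data@betaY; sy <- data@seY
  L <- length(bx)
  if (L < 3L) stop("insufficient instruments for Egger (need >= 3)")
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coefs
  Q <- sum(w * resid^2)
  Qdf <- L - 2
  scale <- max(1, sqrt(Q / Qdf))
  ses <- unname(sqrt(diag(solve(XtWX))) * scale)
  beta <- unname(coefs[2]); se <- ses[2]
  coefs <- unname(coefs)
  ci <- waldCI(beta, se)
  new("MREstimate", method = "egger", beta = beta, se = se,
      ciLow = ci[1], ciHigh = ci[2], pval = zPval(beta, se), nSnps = L,
      intercept = coefs[1], interceptSE = ses[1],
      interceptPval = zPval(coefs[1], ses[1]),
      Q = Q, Qdf = as.numeric(Qdf),
      Qpval = stats::pchisq(Q, Qdf, lower.tail = FALSE),
      meanF = meanFStatistic(data))
}

## Weighted median of values with weights, by linear interpolation of the
## cumulative weight midpoints p_j = (S_j - w_j/2) / S_L at p = 0.5.
weightedMedianCore <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' Inverse-variance weighted median of the per-SNP Wald ratios, consistent
#' when at least half of the total instrument weight comes from valid
#' instruments. The standard error is obtained by a seeded parametric
#' bootstrap that resamples the exposure and outcome effects from their
#' reported standard errors.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least three SNPs.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \linkS4class{MREstimate}.
#' @export
mrWeightedMedian <- function(data, nBoot = 1000, seed = 1) {
  checkUnivariable(data)
  bx <- data@betaX[, 1]; by <- data@betaY
  sx <- data@seX[, 1]; sy <- data@seY
  L <- length(bx)
  if (L < 3L) stop("insufficient instruments for weighted median (need >= 3)")
  ## canonical orientation (bx >= 0): ratios are unchanged but the
  ## bootstrap draws become independent of the input allele coding
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  ratio <- by / bx
  rse <- sy / abs(bx)
  w <- 1 / rse^2
  beta <- weightedMedianCore(ratio, w)
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bxb <- stats::rnorm(L, bx, sx)
      byb <- stats::rnorm(L, by, sy)
      rb <- byb / bxb
      wb <- (abs(bxb) / sy)^2
      weightedMedianCore(rb, wb)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  q <- cochranQ(data, beta)
  ci <- waldCI(beta, se)
  new("MREstimate", method = "weighted_median", beta = beta, se = se,
      ciLow = ci[1], ciHigh = ci[2], pval = zPval(beta, se), nSnps = L,
      Q = q$Q, Qdf = as.numeric(q$df), Qpval = q$pval,
      meanF = meanFStatistic(data))
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_j w_j (ratio_j - beta_hat)^2 with first-order weights
#' w_j = beta_Xj^2 / se_Yj^2, referred to a chi-squared distribution with
#' L - 1 degrees of freedom.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least two SNPs.
#' @param betaHat the pooled causal estimate the deviations are taken
#'   from (typically the IVW estimate).
#' @return list with elements \code{Q}, \code{df}, \code{pval}.
#' @export
cochranQ <- function(data, betaHat) {
  checkUnivariable(data)
  bx <- data@betaX[, 1]; by <- data@betaY; sy <- data@seY
  L <- length(bx)
  if (L < 2L) stop("Cochran's Q needs >= 2 SNPs")
  ratio <- by / bx
  w <- bx^2 / sy^2
  Q <- sum(w * (ratio - betaHat)^2)
  df <- L - 1
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Mean instrument-strength F statistic
#'
#' Mean over SNPs of (beta_X / se_X)^2; values above 10 conventionally
#' indicate adequate instrument strength.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure.
#' @return numeric scalar.
#' @export
meanFStatistic <- function(data) {
  checkUnivariable(data)
  mean((data@betaX[, 1] / data@seX[, 1])^2)
}

#' Steiger directionality filtering
#'
#' For each SNP, the variance explained in each trait is approximated as
#' r^2 = t^2 / (t^2 + n - 2) with t = beta/se (for a binary outcome this
#' is on the observed log-odds scale and is approximate). A SNP is flagged
#' as directionally incorrect — likely acting on the outcome first — when
#' it explains more variance in the outcome than in the exposure and the
#' Steiger z-test for the difference of the two correlations rejects at
#' \code{alpha}. Flagged SNPs are removed from the returned dataset.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and
#'   sample sizes for both traits.
#' @param alpha significance level of the directionality test
#'   (default 0.05).
#' @return list with elements \code{result} (a
#'   \linkS4class{SteigerResult}) and \code{data} (the filtered
#'   \linkS4class{HarmonizedMRData}).
#' @export
steigerFilter <- function(data, alpha = 0.05) {
  checkUnivariable(data)
  nx <- data@nX[1]; ny <- data@nY
  if (!is.finite(nx) || !is.finite(ny))
    stop("sample sizes required for Steiger filtering")
  tx <- data@betaX[, 1] / data@seX[, 1]
  ty <- data@betaY / data@seY
  r2x <- tx^2 / (tx^2 + nx - 2)
  r2y <- ty^2 / (ty^2 + ny - 2)
  rx <- sqrt(r2x); ry <- sqrt(r2y)
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
  pval <- 2 * stats::pnorm(-abs(z))
  incorrect <- (r2y > r2x) & (pval < alpha)
  tab <- data.frame(snp_id = data@snpIds, r2_exposure = r2x,
                    r2_outcome = r2y, direction_correct = !incorrect,
                    steiger_pval = pval, stringsAsFactors = FALSE)
  retained <- data@snpIds[!incorrect]
  if (!length(retained)) stop("Steiger filtering removed every SNP")
  list(result = new("SteigerResult", table = tab, retainedSnps = retained),
       data = subsetSnps(data, retained))
}
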