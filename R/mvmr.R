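## Multivariable MR estimation and diagnostics.

checkMultivariable <- function(data) {
  stopifnot(is(data, "HarmonizedMRData"))
  if (ncol(data@betaX) < 2L)
    stop("multivariable MR requires >= 2 exposures")
}

#' Multivariable IVW MR estimate
#'
#' Weighted least-squares regression of the outcome effects on the K
#' exposure-effect columns without intercept, weights 1/se_Y^2, giving
#' each exposure's direct effect conditional on the others. Standard
#' errors are scaled by max(1, sqrt(Q_A / (L - K))) where Q_A is the
#' multivariable heterogeneity statistic. Cross-exposure sampling
#' covariance is taken as zero (non-overlapping GWAS samples).
#'
#' @param data a \linkS4class{HarmonizedMRData} with K >= 2 exposures and
#'   at least K + 1 SNPs.
#' @return an \linkS4class{MVMREstimate}.
#' @export
mvmrIVW <- function(data) {
  checkMultivariable(data)
  X <- data@betaX; y <- data@betaY; sy <- data@seY
  L <- nrow(X); K <- ncol(X)
  if (L < K + 1L) stop("need at least K + 1 SNPs for MVMR")
  w <- 1 / sy^2
  XtWX <- crossprod(X, w * X)
  if (qr(XtWX)$rank < K) stop("collinear exposures")
  betas <- drop(solve(XtWX, crossprod(X, w * y)))
  qa <- mvmrQA(data, betas)
  scale <- if (qa$df >= 1) max(1, sqrt(qa$Q / qa$df)) else 1
  ses <- sqrt(diag(solve(XtWX))) * scale
  ci <- waldCI(betas, ses)
  condF <- vapply(seq_len(K), function(k) conditionalF(data, k), numeric(1))
  if (any(condF < 10))
    warning("conditional F below 10 for exposure(s): ",
            paste(colnames(X)[condF < 10], collapse = ", "),
            " - weak-instrument bias possible")
  new("MVMREstimate", exposureNames = colnames(X), betas = betas,
      ses = ses, ciLows = ci[, 1], ciHighs = ci[, 2],
      pvals = zPval(betas, ses), nSnps = L, conditionalF = condF,
      QA = qa$Q, QAdf = as.numeric(qa$df), QApval = qa$pval)
}

#' Conditional instrument-strength F statistic
#'
#' Strength of one exposure's instruments conditional on the remaining
#' exposures: the chosen exposure's effect column is regressed on the
#' other columns with weights 1/se_X^2 of the chosen exposure, and the
#' weighted residual sum of squares Q_x is referred to its degrees of
#' freedom, F = Q_x / (L - K + 1). Cross-trait sampling covariance is
#' assumed zero (two non-overlapping samples). Perfectly collinear
#' exposures give F near 0; orthogonal strong instruments recover the
#' univariable mean F.
#'
#' @param data a \linkS4class{HarmonizedMRData} with K >= 2 exposures.
#' @param exposureIndex column index of the exposure to assess.
#' @return numeric scalar.
#' @export
conditionalF <- function(data, exposureIndex) {
  checkMultivariable(data)
  X <- data@betaX
  K <- ncol(X); L <- nrow(X)
  stopifnot(exposureIndex >= 1, exposureIndex <= K)
  target <- X[, exposureIndex]
  others <- X[, -exposureIndex, drop = FALSE]
  w <- 1 / data@seX[, exposureIndex]^2
  AtWA <- crossprod(others, w * others)
  coefs <- tryCatch(solve(AtWA, crossprod(others, w * target)),
                    error = function(e) qr.solve(others * sqrt(w),
                                                 target * sqrt(w)))
  resid <- target - others %*% coefs
  Qx <- sum(w * resid^2)
  Qx / (L - K + 1)
}

#' Multivariable heterogeneity statistic Q_A
#'
#' Q_A = sum_j (beta_Yj - sum_k beta_Xjk * beta_k)^2 / se_Yj^2, the
#' multivariable adaptation of Cochran's Q, referred to chi-squared with
#' L - K degrees of freedom. Uses the supplied (plug-in) direct effects.
#'
#' @param data a \linkS4class{HarmonizedMRData} with K >= 2 exposures.
#' @param betas length-K vector of direct effects.
#' @return list with elements \code{Q}, \code{df}, \code{pval}.
#' @export
mvmrQA <- function(data, betas) {
  checkMultivariable(data)
  X <- data@betaX; y <- data@betaY; sy <- data@seY
  stopifnot(length(betas) == ncol(X))
  Q <- sum((y - drop(X %*% betas))^2 / sy^2)
  df <- nrow(X) - ncol(X)
  list(Q = Q, df = df,
       pval = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE)
              else NA_real_)
}
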