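## Two-step MR mediation: product and difference of coefficients,
## delta-method standard errors, proportion mediated.

#' Indirect effect by the product of coefficients
#'
#' Multiplies the exposure-on-mediator effect (step one, univariable MR)
#' by the mediator-on-outcome direct effect conditional on the exposure
#' (step two, from MVMR). The standard error is the delta-method (Sobel)
#' form sqrt(a^2 se_b^2 + b^2 se_a^2); the exact variant adds the
#' second-order term se_a^2 se_b^2.
#'
#' @param betaEM,seEM exposure-on-mediator effect and SE (scalars, or an
#'   \linkS4class{MREstimate} passed as \code{betaEM}).
#' @param betaMY,seMY mediator-on-outcome direct effect and SE (scalars,
#'   or an \linkS4class{MVMREstimate} plus \code{exposure} name).
#' @param exact include the second-order Sobel term (default FALSE).
#' @param exposure when \code{betaMY} is an \linkS4class{MVMREstimate},
#'   the name or index of the mediator entry.
#' @return named list: \code{indirect}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{pval}.
#' @export
productMethod <- function(betaEM, seEM = NULL, betaMY = NULL, seMY = NULL,
                          exact = FALSE, exposure = NULL) {
  if (is(betaEM, "MREstimate")) { seEM <- betaEM@se; betaEM <- betaEM@beta }
  if (is(betaMY, "MVMREstimate")) {
    stopifnot(!is.null(exposure))
    seMY <- mrSE(betaMY)[[exposure]]
    betaMY <- mrBeta(betaMY)[[exposure]]
  }
  indirect <- betaEM * betaMY
  v <- betaEM^2 * seMY^2 + betaMY^2 * seEM^2
  if (exact) v <- v + seEM^2 * seMY^2
  se <- sqrt(v)
  ci <- waldCI(indirect, se)
  list(indirect = indirect, se = se, ci_low = ci[1], ci_high = ci[2],
       pval = zPval(indirect, se))
}

#' Indirect effect by the difference of coefficients
#'
#' Subtracts the MVMR direct effect of the exposure on the outcome from
#' its univariable (total) MR effect. The standard error is by
#' propagation of errors, sqrt(se_total^2 + se_direct^2); the covariance
#' between the two estimates (they share instruments) is ignored, which
#' can be anti-conservative.
#'
#' @param betaTotal,seTotal total effect and SE (scalars, or an
#'   \linkS4class{MREstimate} passed as \code{betaTotal}).
#' @param betaDirect,seDirect MVMR direct effect and SE (scalars, or an
#'   \linkS4class{MVMREstimate} plus \code{exposure} name).
#' @param exposure when \code{betaDirect} is an
#'   \linkS4class{MVMREstimate}, the name or index of the exposure entry.
#' @return named list: \code{indirect}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{pval}.
#' @export
differenceMethod <- function(betaTotal, seTotal = NULL, betaDirect = NULL,
                             seDirect = NULL, exposure = NULL) {
  if (is(betaTotal, "MREstimate")) {
    seTotal <- betaTotal@se; betaTotal <- betaTotal@beta
  }
  if (is(betaDirect, "MVMREstimate")) {
    stopifnot(!is.null(exposure))
    seDirect <- mrSE(betaDirect)[[exposure]]
    betaDirect <- mrBeta(betaDirect)[[exposure]]
  }
  indirect <- betaTotal - betaDirect
  se <- sqrt(seTotal^2 + seDirect^2)
  ci <- waldCI(indirect, se)
  list(indirect = indirect, se = se, ci_low = ci[1], ci_high = ci[2],
       pval = zPval(indirect, se))
}

#' Proportion of the total effect that is mediated
#'
#' proportion = indirect / total, with a delta-method confidence interval
#' for the ratio: var(p) = se_ind^2/t^2 + ind^2 se_t^2/t^4
#' - 2 ind cov/t^3. The covariance defaults to zero (the two-sample
#' design estimates the indirect and total effects from different outcome
#' draws only partially, so this is approximate). Values outside [0, 1]
#' are reported as computed with a warning.
#'
#' @param indirect,seIndirect indirect effect and SE (a list as returned
#'   by \code{\link{productMethod}} may be passed as \code{indirect}).
#' @param total,seTotal total effect and SE (an \linkS4class{MREstimate}
#'   may be passed as \code{total}).
#' @param cov covariance between the indirect and total estimates
#'   (default 0).
#' @return named list: \code{proportion}, \code{ci_low}, \code{ci_high}.
#' @export
proportionMediated <- function(indirect, seIndirect = NULL, total = NULL,
                               seTotal = NULL, cov = 0) {
  if (is.list(indirect)) { seIndirect <- indirect$se; indirect <- indirect$indirect }
  if (is(total, "MREstimate")) { seTotal <- total@se; total <- total@beta }
  if (total == 0) stop("undefined proportion: total effect is zero")
  if (abs(total) <= 10 * seTotal)
    warning("total effect is imprecise relative to its SE; ",
            "the proportion-mediated CI may be unstable")
  p <- indirect / total
  v <- seIndirect^2 / total^2 + indirect^2 * seTotal^2 / total^4 -
    2 * indirect * cov / total^3
  se <- sqrt(max(v, 0))
  ci <- waldCI(p, se)
  if (p < 0 || p > 1)
    warning("proportion mediated outside [0, 1]; reported as computed")
  list(proportion = p, ci_low = ci[1], ci_high = ci[2], se = se)
}

#' Assemble a MediationResult from its component estimates
#'
#' Combines the four input effects (total, direct, exposure-on-mediator,
#' mediator-on-outcome direct) into both indirect-effect constructions
#' and the proportion mediated.
#'
#' @param total,direct,exposureMediator,mediatorDirect length-2 vectors
#'   \code{c(estimate, se)}.
#' @param scale \code{"continuous"} or \code{"log_odds"}.
#' @return a \linkS4class{MediationResult}.
#' @export
mediationResult <- function(total, direct, exposureMediator, mediatorDirect,
                            scale = c("continuous", "log_odds")) {
  scale <- match.arg(scale)
  total <- unname(total); direct <- unname(direct)
  exposureMediator <- unname(exposureMediator)
  mediatorDirect <- unname(mediatorDirect)
  prod <- productMethod(exposureMediator[1], exposureMediator[2],
                        mediatorDirect[1], mediatorDirect[2])
  diff <- differenceMethod(total[1], total[2], direct[1], direct[2])
  pm <- proportionMediated(prod$indirect, prod$se, total[1], total[2])
  new("MediationResult", totalEffect = total, directEffect = direct,
      exposureMediator = exposureMediator, mediatorDirect = mediatorDirect,
      indirectProduct = c(prod$indirect, prod$se, prod$ci_low, prod$ci_high,
                          prod$pval),
      indirectDifference = c(diff$indirect, diff$se, diff$ci_low,
                             diff$ci_high, diff$pval),
      proportionMediated = c(pm$proportion, pm$ci_low, pm$ci_high),
      scale = scale)
}

#' Two-step MR mediation analysis from summary statistics
#'
#' Runs the full mediation decomposition for one exposure, one mediator
#' and one outcome: (1) total effect by univariable IVW of exposure on
#' outcome; (2) exposure-on-mediator effect by univariable IVW; (3) MVMR
#' of exposure and mediator on the outcome over the union of both traits'
#' instruments, giving the direct exposure effect and the mediator's
#' direct effect; (4) indirect effects by the product and difference
#' methods and the proportion mediated with a delta-method CI.
#'
#' @param exposure,mediator,outcome \linkS4class{GwasSummaryStats}.
#' @param pThreshold instrument p-value threshold (default 5e-8).
#' @param pruneWindow positional pruning window in bp (default 10 Mb).
#' @param palindromeWindow ambiguity window for palindromic SNPs.
#' @param ivwMode IVW flavour for the univariable steps (default
#'   \code{"mre"}).
#' @return a \linkS4class{MediationResult}; the component fits are
#'   attached as attribute \code{"fits"} (list with \code{total},
#'   \code{exposureMediator}, \code{mvmr}).
#' @export
runMediation <- function(exposure, mediator, outcome, pThreshold = 5e-8,
                         pruneWindow = 1e7, palindromeWindow = 0.08,
                         ivwMode = "mre") {
  instX <- selectInstruments(exposure, pThreshold, pruneWindow)
  total <- mrIVW(harmonizeTraits(instX, outcome, palindromeWindow),
                 mode = ivwMode)
  em <- mrIVW(harmonizeTraits(instX, mediator, palindromeWindow),
              mode = ivwMode)
  instM <- selectInstruments(mediator, pThreshold, pruneWindow)
  unionIds <- union(snpIds(instX), snpIds(instM))
  expoAll <- subsetStats(exposure, unionIds)
  medAll <- subsetStats(mediator, unionIds)
  mv <- mvmrIVW(harmonizeTraits(list(expoAll, medAll), outcome,
                                palindromeWindow))
  scale <- if (outcome@traitType == "binary") "log_odds" else "continuous"
  res <- mediationResult(
    total = c(total@beta, total@se),
    direct = c(mv@betas[1], mv@ses[1]),
    exposureMediator = c(em@beta, em@se),
    mediatorDirect = c(mv@betas[2], mv@ses[2]),
    scale = scale)
  attr(res, "fits") <- list(total = total, exposureMediator = em, mvmr = mv)
  res
}

## restrict a GwasSummaryStats to a set of snp ids (keeps those present)
subsetStats <- function(stats, ids) {
  d <- stats@data[stats@data$snp_id %in% ids, , drop = FALSE]
  d <- d[order(d$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  new("GwasSummaryStats", traitName = stats@traitName,
      traitType = stats@traitType, data = d, dropLog = stats@dropLog)
}
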