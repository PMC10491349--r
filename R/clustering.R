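## Mixture-model clustering of per-SNP ratio estimates: K free normal
## components plus a null component (mean fixed at zero) and a bounded
## uniform "junk" component, fitted by EM with known per-SNP variances.

## One EM fit for a fixed K and given initial means. Returns NULL on a
## degenerate fit.
clusterEMFit <- function(ratio, se2, K, initMeans, junkDensity,
                         maxIter = 500, tol = 1e-8) {
  L <- length(ratio)
  nComp <- K + 2L                       # K clusters, null, junk
  mu <- c(initMeans, 0)                 # junk handled separately
  pi <- rep(1 / nComp, nComp)
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- matrix(0, L, nComp)
    for (k in seq_len(K + 1L))
      dens[, k] <- stats::dnorm(ratio, mu[k], sqrt(se2))
    dens[, nComp] <- junkDensity
    num <- sweep(dens, 2, pi, `*`)
    rowTot <- rowSums(num)
    if (any(rowTot == 0) || any(!is.finite(rowTot))) return(NULL)
    gamma <- num / rowTot
    newLL <- sum(log(rowTot))
    pi <- colMeans(gamma)
    ## weighted-mean update for the K free components only
    if (K > 0) for (k in seq_len(K)) {
      wk <- gamma[, k] / se2
      if (sum(wk) > 0) mu[k] <- sum(wk * ratio) / sum(wk)
    }
    if (is.finite(ll) && abs(newLL - ll) < tol) { ll <- newLL; break }
    ll <- newLL
    if (iter == maxIter) return(NULL)   # non-convergence
  }
  ## cluster means' standard errors from the effective member weights
  muSE <- rep(NA_real_, K)
  if (K > 0) for (k in seq_len(K))
    muSE[k] <- sqrt(1 / sum(gamma[, k] / se2))
  list(mu = mu[seq_len(K)], muSE = muSE, pi = pi, gamma = gamma, logLik = ll)
}

#' Mixture-model clustering of Wald ratio estimates
#'
#' Fits, by expectation-maximization over component means and mixing
#' proportions, a mixture over the per-SNP ratio estimates with their
#' (known) first-order variances: K free normal components, one null
#' component with mean fixed at zero, and one junk component, uniform over
#' the observed ratio range widened by ten times the largest ratio SE. K
#' is chosen over 0..\code{maxK} by a BIC-style penalized log-likelihood;
#' each K is fitted from 20 seeded random restarts. A SNP is labelled with
#' its maximum-probability component only when that probability reaches
#' \code{probThreshold}, and \code{"unassigned"} otherwise. Per-cluster
#' IVW estimates are computed over the assigned members.
#'
#' @param data a \linkS4class{HarmonizedMRData} with one exposure and at
#'   least three SNPs.
#' @param maxK maximum number of substantive clusters (default 5).
#' @param probThreshold conditional assignment probability required for a
#'   label (default 0.9).
#' @param seed RNG seed for the restarts.
#' @param nRestarts random restarts per K (default 20).
#' @return a \linkS4class{ClusterAssignment}.
#' @export
clusterRatios <- function(data, maxK = 5, probThreshold = 0.9, seed = 1,
                          nRestarts = 20) {
  checkUnivariable(data)
  bx <- data@betaX[, 1]; by <- data@betaY; sy <- data@seY
  L <- length(bx)
  if (L < 3L) stop("clustering needs >= 3 SNPs")
  stopifnot(maxK >= 1)
  ratio <- by / bx
  se <- sy / abs(bx)
  se2 <- se^2
  span <- range(ratio) + c(-10, 10) * max(se)
  junkDensity <- 1 / diff(span)

  best <- NULL
  withSeed(seed, {
    for (K in 0:maxK) {
      bestK <- NULL
      for (r in seq_len(max(1L, if (K == 0) 1L else nRestarts))) {
        ## jitter initial means by the typical ratio SE so restarts stay
        ## in the basins around observed ratios
        init <- if (K > 0)
          sample(ratio, K) + stats::rnorm(K, 0, stats::median(se))
        else numeric(0)
        fit <- clusterEMFit(ratio, se2, K, init, junkDensity)
        if (is.null(fit)) next
        if (is.null(bestK) || fit$logLik > bestK$logLik) bestK <- fit
      }
      if (is.null(bestK)) next
      ## a fit whose substantive components include an (effectively)
      ## empty one is a degenerate restatement of a smaller K
      if (K > 0 &&
          any(colSums(bestK$gamma)[seq_len(K)] < 0.5)) next
      nPar <- K + (K + 2L - 1L)         # free means + free mixing props
      crit <- -2 * bestK$logLik + nPar * log(L)
      if (is.null(best) || crit < best$crit)
        best <- c(bestK, list(K = K, crit = crit))
    }
  })
  if (is.null(best)) stop("EM failed to converge in all restarts")

  K <- best$K
  compNames <- c(if (K > 0) paste0("cluster_", seq_len(K)), "null", "junk")
  gamma <- best$gamma
  colnames(gamma) <- compNames
  top <- max.col(gamma, ties.method = "first")
  topProb <- gamma[cbind(seq_len(L), top)]
  label <- ifelse(topProb >= probThreshold, compNames[top], "unassigned")
  assignments <- data.frame(snp_id = data@snpIds, label = label,
                            probability = topProb, stringsAsFactors = FALSE)
  clusters <- data.frame(label = compNames,
                         mean = c(best$mu, 0, NA_real_),
                         se = c(best$muSE, NA_real_, NA_real_),
                         size = vapply(compNames,
                                       function(l) sum(label == l), 0L),
                         ivw_beta = NA_real_, ivw_se = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(clusters))) {
    members <- data@snpIds[label == clusters$label[i]]
    if (length(members) >= 1) {
      est <- mrIVW(subsetSnps(data, members), mode = "mre")
      clusters$ivw_beta[i] <- est@beta
      clusters$ivw_se[i] <- est@se
    }
  }
  rownames(gamma) <- data@snpIds
  new("ClusterAssignment", K = as.integer(K), assignments = assignments,
      probabilities = gamma, clusters = clusters, logLik = best$logLik,
      criterion = best$crit, seed = as.integer(seed))
}
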