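## Simulation of two-sample GWAS summary statistics under a known
## exposure -> mediator -> outcome causal model.

#' Construct a SimulationConfig
#'
#' All arguments have working defaults; see
#' \linkS4class{SimulationConfig} for their meaning and
#' \code{\link{generateDataset}} for the generative model.
#'
#' @param seed master RNG seed.
#' @param nSnps number of independent SNPs.
#' @param mafRange c(low, high) uniform MAF bounds.
#' @param nExposure,nMediator,nOutcome per-trait GWAS sample sizes.
#' @param gammaMean,gammaSD mean and SD of SNP-on-exposure effects.
#' @param deltaSD SD of direct SNP-on-mediator effects.
#' @param alpha exposure-on-mediator effect.
#' @param betaMed mediator-on-outcome effect.
#' @param betaDirect direct exposure-on-outcome effect.
#' @param pleiotropyMean,pleiotropySD,pleiotropyFraction direct
#'   SNP-on-outcome pleiotropy distribution and the fraction of SNPs
#'   affected.
#' @param outlierFraction,outlierEffect planted heterogeneity outliers.
#' @param clusterSpec list of c(proportion, slope) mechanism clusters.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @param caseFraction binary-outcome case fraction.
#' @param orientGamma draw SNP-on-exposure effects half-normal (positive).
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1, nSnps = 100, mafRange = c(0.1, 0.4),
                             nExposure = 50000, nMediator = 50000,
                             nOutcome = 50000, gammaMean = 0, gammaSD = 0.06,
                             deltaSD = 0, alpha = 0, betaMed = 0, betaDirect = 0,
                             pleiotropyMean = 0, pleiotropySD = 0,
                             pleiotropyFraction = 1, outlierFraction = 0,
                             outlierEffect = 0, clusterSpec = list(),
                             outcomeType = c("continuous", "binary"),
                             caseFraction = 0.5, orientGamma = FALSE) {
  outcomeType <- match.arg(outcomeType)
  new("SimulationConfig", seed = as.integer(seed), nSnps = as.integer(nSnps),
      mafRange = as.numeric(mafRange), nExposure = as.numeric(nExposure),
      nMediator = as.numeric(nMediator), nOutcome = as.numeric(nOutcome),
      gammaMean = as.numeric(gammaMean), gammaSD = as.numeric(gammaSD),
      deltaSD = as.numeric(deltaSD),
      alpha = as.numeric(alpha), betaMed = as.numeric(betaMed),
      betaDirect = as.numeric(betaDirect),
      pleiotropyMean = as.numeric(pleiotropyMean),
      pleiotropySD = as.numeric(pleiotropySD),
      pleiotropyFraction = as.numeric(pleiotropyFraction),
      outlierFraction = as.numeric(outlierFraction),
      outlierEffect = as.numeric(outlierEffect),
      clusterSpec = clusterSpec, outcomeType = outcomeType,
      caseFraction = as.numeric(caseFraction),
      orientGamma = isTRUE(orientGamma))
}

## analytic SE of a standardized per-allele GWAS estimate
analyticSE <- function(maf, n, caseFraction = NULL) {
  denom <- 2 * maf * (1 - maf) * n
  if (!is.null(caseFraction)) denom <- denom * caseFraction * (1 - caseFraction)
  1 / sqrt(denom)
}

## deterministic largest-remainder allocation: assigns round(n * sum(props))
## items across the clusters; the rest of the n stay unallocated (null)
allocateCounts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  left <- round(sum(raw)) - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate two-sample GWAS summary statistics with known truth
#'
#' Draws per-SNP minor-allele frequencies p_j ~ Uniform(mafRange) and
#' SNP-on-exposure effects gamma_j ~ Normal(0, gammaSD^2) (half-normal
#' when \code{orientGamma}). True effects follow the causal diagram:
#' mediator effect alpha * gamma_j + delta_j with delta_j ~ Normal(0,
#' deltaSD^2) (the mediator's own instruments); outcome effect
#' (betaDirect + alpha * betaMed) * gamma_j + betaMed * delta_j +
#' theta_j, where theta_j collects configured horizontal pleiotropy and
#' planted outlier shifts. When a \code{clusterSpec} is given it replaces
#' the single-mechanism outcome model: each mechanism cluster c
#' contributes slope_c * gamma_j for its SNPs and the remaining SNPs are
#' null. Observed effects are the truth plus independent normal noise
#' with the analytic standard errors se_j = 1 / sqrt(2 p_j (1 - p_j)
#' n_trait) for standardized continuous traits, additionally divided by
#' sqrt(caseFraction (1 - caseFraction)) inside the root on the log-odds
#' scale for binary outcomes; p-values are two-sided normal. The three
#' samples use independent noise (non-overlapping GWAS); identical
#' configurations give byte-identical output.
#'
#' Variants are placed on alternating chromosomes at least 50 Mb apart
#' (linkage equilibrium is assumed, matching the post-clumping regime the
#' estimators expect), and allele codings are randomly swapped between
#' traits so harmonization is genuinely exercised.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{exposure}, \code{mediator},
#'   \code{outcome} (\linkS4class{GwasSummaryStats}) and \code{truth}
#'   (\linkS4class{SimulatedTruth}).
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  J <- config@nSnps
  snp <- sprintf("rs%06d", seq_len(J))
  chrom <- as.character(((seq_len(J) - 1L) %% 22L) + 1L)
  pos <- 1000000L + ((seq_len(J) - 1L) %/% 22L) * 50000000L

  ## structural draws under the master seed
  str <- withSeed(deriveSeed(config@seed, 0L), {
    maf <- stats::runif(J, config@mafRange[1], config@mafRange[2])
    gamma <- stats::rnorm(J, config@gammaMean, config@gammaSD)
    if (config@orientGamma) gamma <- abs(gamma)
    delta <- if (config@deltaSD > 0) stats::rnorm(J, 0, config@deltaSD)
             else numeric(J)
    theta <- numeric(J)
    if (config@pleiotropySD > 0 || config@pleiotropyMean != 0) {
      nPlei <- round(config@pleiotropyFraction * J)
      idx <- if (nPlei >= J) seq_len(J) else sample.int(J, nPlei)
      theta[idx] <- stats::rnorm(length(idx), config@pleiotropyMean,
                                 config@pleiotropySD)
    }
    nOut <- round(config@outlierFraction * J)
    outIdx <- if (nOut > 0) sample.int(J, nOut) else integer(0)
    theta[outIdx] <- theta[outIdx] + config@outlierEffect
    ## random allele codings per trait (non-palindromic pairs)
    pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
    pairIdx <- sample.int(nrow(pairs), J, replace = TRUE)
    swapMed <- stats::runif(J) < 0.3
    swapOut <- stats::runif(J) < 0.3
    list(maf = maf, gamma = gamma, delta = delta, theta = theta,
         outIdx = outIdx, pairIdx = pairIdx, swapMed = swapMed,
         swapOut = swapOut)
  })
  maf <- str$maf; gamma <- str$gamma; delta <- str$delta; theta <- str$theta

  total <- config@betaDirect + config@alpha * config@betaMed
  clusterLabels <- character(0)
  if (length(config@clusterSpec)) {
    props <- vapply(config@clusterSpec, `[`, numeric(1), 1L)
    slopes <- vapply(config@clusterSpec, `[`, numeric(1), 2L)
    counts <- allocateCounts(J, props)
    slopePer <- rep(0, J)
    clusterLabels <- rep("null", J)
    at <- 1L
    for (c in seq_along(counts)) {
      if (counts[c] == 0L) next
      idx <- seq(at, length.out = counts[c])
      slopePer[idx] <- slopes[c]
      clusterLabels[idx] <- paste0("cluster_", c)
      at <- at + counts[c]
    }
    trueY <- slopePer * gamma + theta
    trueM <- config@alpha * gamma + delta
  } else {
    trueM <- config@alpha * gamma + delta
    trueY <- total * gamma + config@betaMed * delta + theta
  }

  seX <- analyticSE(maf, config@nExposure)
  seM <- analyticSE(maf, config@nMediator)
  seY <- if (config@outcomeType == "binary")
    analyticSE(maf, config@nOutcome, config@caseFraction)
  else analyticSE(maf, config@nOutcome)

  drawTrait <- function(true, se, childIndex)
    withSeed(deriveSeed(config@seed, childIndex), true + stats::rnorm(J, 0, se))
  bX <- drawTrait(gamma, seX, 1L)
  bM <- drawTrait(trueM, seM, 2L)
  bY <- drawTrait(trueY, seY, 3L)

  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  ea <- pairs[str$pairIdx, 1]; oa <- pairs[str$pairIdx, 2]
  makeStats <- function(name, type, beta, se, n, swap) {
    d <- data.frame(snp_id = snp, chrom = chrom, pos = pos,
                    effect_allele = ifelse(swap, oa, ea),
                    other_allele = ifelse(swap, ea, oa),
                    eaf = ifelse(swap, 1 - maf, maf),
                    beta = ifelse(swap, -beta, beta), se = se,
                    pval = zPval(beta, se), n = n, stringsAsFactors = FALSE)
    new("GwasSummaryStats", traitName = name, traitType = type, data = d,
        dropLog = data.frame(snp_id = character(), reason = character()))
  }
  noSwap <- rep(FALSE, J)
  truth <- new("SimulatedTruth", snpIds = snp, maf = maf, gamma = gamma,
               deltaM = delta, thetaY = theta, alpha = config@alpha,
               betaMed = config@betaMed, betaDirect = config@betaDirect,
               totalEffect = total,
               proportionMediated = if (total != 0)
                 config@alpha * config@betaMed / total else NA_real_,
               outlierIds = snp[str$outIdx],
               clusterLabels = clusterLabels)
  list(exposure = makeStats("exposure", "continuous", bX, seX,
                            config@nExposure, noSwap),
       mediator = makeStats("mediator", "continuous", bM, seM,
                            config@nMediator, str$swapMed),
       outcome = makeStats("outcome",
                           if (config@outcomeType == "binary") "binary"
                           else "continuous",
                           bY, seY, config@nOutcome, str$swapOut),
       truth = truth)
}

#' Named simulation scenarios
#'
#' Returns a fully populated \linkS4class{SimulationConfig} for a named
#' scenario. The anchor scenario \code{"dense_area_default"} encodes the
#' childhood-adiposity / dense-area / breast-cancer causal structure:
#' a binary outcome on the log-odds scale with true total effect -0.41,
#' of which 56\% is mediated (alpha = -0.56, betaMed = 0.41, betaDirect
#' = -0.1804), 100 SNPs and GWAS samples of 50,000 per trait. Other
#' presets:
#' \describe{
#'   \item{null_mediation}{alpha = 0 (no exposure-mediator path), true
#'     proportion mediated 0.}
#'   \item{continuous_mediation}{the anchor effects on a continuous
#'     outcome scale, where product and difference decompositions
#'     coincide.}
#'   \item{clustered_dense_area}{two planted mechanisms (slopes +0.4 and
#'     -0.3, ten SNPs each) plus five null SNPs, mimicking ratio-estimate
#'     clusters of opposite sign.}
#'   \item{outlier_default}{21 instruments, three of which carry a
#'     planted pleiotropic shift of five outcome-SEs.}
#'   \item{invalid_40pct}{40\% of instruments carry directional
#'     pleiotropy (mean 0.06), the regime where the weighted median
#'     stays consistent while IVW does not.}
#'   \item{directional_pleiotropy}{all instruments carry pleiotropy of
#'     mean 0.02 (InSIDE satisfied), the regime the Egger intercept
#'     estimates.}
#' }
#'
#' @param preset scenario name.
#' @param seed RNG seed to place in the config (default 1).
#' @return a \linkS4class{SimulationConfig}.
#' @export
mediationScenario <- function(preset, seed = 1) {
  presets <- c("dense_area_default", "null_mediation",
               "continuous_mediation", "clustered_dense_area",
               "outlier_default", "invalid_40pct", "directional_pleiotropy")
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  switch(preset,
    dense_area_default = simulationConfig(
      seed = seed, nSnps = 100, mafRange = c(0.1, 0.4),
      nExposure = 50000, nMediator = 50000, nOutcome = 50000,
      gammaSD = 0.06, deltaSD = 0.06,
      alpha = -0.56, betaMed = 0.41, betaDirect = -0.1804,
      outcomeType = "binary", caseFraction = 0.5),
    null_mediation = simulationConfig(
      seed = seed, nSnps = 100, mafRange = c(0.1, 0.4),
      nExposure = 50000, nMediator = 50000, nOutcome = 50000,
      gammaSD = 0.06, deltaSD = 0.06,
      alpha = 0, betaMed = 0.41, betaDirect = -0.41,
      outcomeType = "binary", caseFraction = 0.5),
    continuous_mediation = simulationConfig(
      seed = seed, nSnps = 100, mafRange = c(0.1, 0.4),
      nExposure = 50000, nMediator = 50000, nOutcome = 50000,
      gammaSD = 0.06, deltaSD = 0.06,
      alpha = -0.56, betaMed = 0.41, betaDirect = -0.1804,
      outcomeType = "continuous"),
    clustered_dense_area = simulationConfig(
      seed = seed, nSnps = 25, mafRange = c(0.25, 0.25),
      nExposure = 50000, nOutcome = 50000, gammaMean = 0.365,
      gammaSD = 0.02,
      clusterSpec = list(c(0.4, 0.4), c(0.4, -0.3)),
      outcomeType = "continuous"),
    outlier_default = simulationConfig(
      seed = seed, nSnps = 21, mafRange = c(0.25, 0.25),
      nExposure = 50000, nOutcome = 50000, gammaSD = 0.3,
      betaDirect = 0.4, outlierFraction = 3 / 21,
      outlierEffect = 5 * analyticSE(0.25, 50000),
      outcomeType = "continuous"),
    invalid_40pct = simulationConfig(
      seed = seed, nSnps = 50, mafRange = c(0.25, 0.25),
      nExposure = 50000, nOutcome = 200000, gammaSD = 0.15,
      betaDirect = 0.1, pleiotropyMean = 0.06, pleiotropySD = 0.01,
      pleiotropyFraction = 0.4, orientGamma = TRUE,
      outcomeType = "continuous"),
    directional_pleiotropy = simulationConfig(
      seed = seed, nSnps = 50, mafRange = c(0.25, 0.25),
      nExposure = 50000, nOutcome = 200000, gammaSD = 0.15,
      betaDirect = 0.1, pleiotropyMean = 0.02, pleiotropySD = 0.01,
      pleiotropyFraction = 1, orientGamma = TRUE,
      outcomeType = "continuous"))
}

#' Write a simulated dataset to disk
#'
#' Emits each trait as the TSV dialect \code{\link{readSummaryStats}}
#' reads, and the ground truth as JSON.
#'
#' @param dataset list as returned by \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (trait in c("exposure", "mediator", "outcome")) {
    p <- file.path(dir, paste0(trait, ".tsv"))
    utils::write.table(dataset[[trait]]@data, p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  t <- dataset$truth
  truthList <- list(snp_ids = t@snpIds, maf = t@maf, gamma = t@gamma,
                    delta_m = t@deltaM, theta_y = t@thetaY,
                    alpha = t@alpha, beta_med = t@betaMed,
                    beta_direct = t@betaDirect, total_effect = t@totalEffect,
                    proportion_mediated = t@proportionMediated,
                    outlier_ids = t@outlierIds,
                    cluster_labels = t@clusterLabels)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truthList, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
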