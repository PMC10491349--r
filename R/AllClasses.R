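## Class definitions for summary-statistic containers, estimates and reports.

VALID_ALLELES <- c("A", "C", "G", "T")

## columns every GwasSummaryStats data slot carries, in this order
SUMMARY_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

#' GwasSummaryStats: one trait's per-SNP GWAS associations
#'
#' Container for a single trait's GWAS summary statistics. Effects are per
#' copy of the effect allele, in SD units for continuous traits and on the
#' log-odds scale for binary traits. Rows violating the per-variant
#' invariants (positive SE, frequency strictly inside (0,1), distinct
#' single-nucleotide alleles, p-value in (0,1]) are removed at construction
#' and recorded in the drop log.
#'
#' @slot traitName single character, trait label.
#' @slot traitType \code{"continuous"} or \code{"binary"}.
#' @slot data data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pval}, \code{n}; \code{chrom}/\code{pos}
#'   may be NA when positions are unknown.
#' @slot dropLog data.frame with columns \code{snp_id} and \code{reason},
#'   one row per input record removed during validation.
#' @export
setClass("GwasSummaryStats",
  representation(traitName = "character", traitType = "character",
                 data = "data.frame", dropLog = "data.frame"),
  prototype(traitName = NA_character_, traitType = "continuous",
            data = data.frame(), dropLog = data.frame(snp_id = character(),
                                                      reason = character())))

setValidity("GwasSummaryStats", function(object) {
  msg <- character()
  if (length(object@traitName) != 1L)
    msg <- c(msg, "traitName must be a single string")
  if (!object@traitType %in% c("continuous", "binary"))
    msg <- c(msg, "traitType must be 'continuous' or 'binary'")
  d <- object@data
  if (nrow(d)) {
    missing_cols <- setdiff(SUMMARY_COLUMNS, names(d))
    if (length(missing_cols))
      msg <- c(msg, paste0("data lacks columns: ",
                           paste(missing_cols, collapse = ", ")))
    else {
      if (anyDuplicated(d$snp_id))
        msg <- c(msg, "snp_id must be unique within a trait")
      if (any(d$se <= 0)) msg <- c(msg, "all se must be > 0")
      if (any(d$eaf <= 0 | d$eaf >= 1))
        msg <- c(msg, "all eaf must lie strictly in (0, 1)")
      if (any(d$pval <= 0 | d$pval > 1))
        msg <- c(msg, "all pval must lie in (0, 1]")
      if (any(d$effect_allele == d$other_allele))
        msg <- c(msg, "effect_allele must differ from other_allele")
      if (!all(d$effect_allele %in% VALID_ALLELES) ||
          !all(d$other_allele %in% VALID_ALLELES))
        msg <- c(msg, "alleles must be single nucleotides A/C/G/T")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedMRData: allele-aligned exposures and outcome
#'
#' Joint per-SNP table of K exposure associations and one outcome
#' association, aligned to the first exposure's effect-allele coding.
#' Rows are sorted by \code{snp_id} so that all downstream estimates are
#' invariant to the input record order.
#'
#' @slot snpIds character vector of retained variant ids (sorted).
#' @slot betaX L x K matrix of exposure effects, one column per exposure.
#' @slot seX matching matrix of standard errors.
#' @slot betaY numeric vector of outcome effects.
#' @slot seY numeric vector of outcome standard errors.
#' @slot eaf effect-allele frequency on the first exposure's coding.
#' @slot nX per-exposure sample sizes (median over SNPs).
#' @slot nY outcome sample size.
#' @slot outcomeType \code{"continuous"} or \code{"binary"} (log-odds betas).
#' @slot flags data.frame (\code{snp_id}, \code{flipped},
#'   \code{palindromic_inferred}) recording per-SNP harmonization decisions.
#' @slot dropped data.frame (\code{snp_id}, \code{reason}) for SNPs shared
#'   on id but removed during harmonization.
#' @export
setClass("HarmonizedMRData",
  representation(snpIds = "character", betaX = "matrix", seX = "matrix",
                 betaY = "numeric", seY = "numeric", eaf = "numeric",
                 nX = "numeric", nY = "numeric", outcomeType = "character",
                 flags = "data.frame", dropped = "data.frame"))

setValidity("HarmonizedMRData", function(object) {
  msg <- character()
  L <- length(object@snpIds)
  K <- ncol(object@betaX)
  if (K < 1L) msg <- c(msg, "at least one exposure required")
  if (nrow(object@betaX) != L || nrow(object@seX) != L ||
      length(object@betaY) != L || length(object@seY) != L ||
      length(object@eaf) != L)
    msg <- c(msg, "per-SNP slots must have one entry per snp_id")
  if (!identical(dim(object@betaX), dim(object@seX)))
    msg <- c(msg, "betaX and seX must have identical dimensions")
  if (length(object@nX) != K)
    msg <- c(msg, "nX must have one entry per exposure")
  if (L) {
    vals <- c(object@betaX, object@seX, object@betaY, object@seY, object@eaf)
    if (!all(is.finite(vals)))
      msg <- c(msg, "retained rows must have complete finite values")
    if (any(object@seX <= 0) || any(object@seY <= 0))
      msg <- c(msg, "standard errors must be positive")
    if (anyDuplicated(object@snpIds)) msg <- c(msg, "snp ids must be unique")
  }
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be 'continuous' or 'binary'")
  if (length(msg)) msg else TRUE
})

#' MREstimate: a univariable MR causal-effect estimate
#'
#' @slot method one of \code{"wald"}, \code{"ivw_fe"}, \code{"ivw_mre"},
#'   \code{"egger"}, \code{"weighted_median"}.
#' @slot beta,se,ciLow,ciHigh,pval causal effect, standard error, 95\%
#'   confidence limits, two-sided p-value.
#' @slot nSnps number of instruments used.
#' @slot intercept,interceptSE,interceptPval Egger intercept terms
#'   (NA for other methods).
#' @slot Q,Qdf,Qpval Cochran's Q heterogeneity statistic.
#' @slot meanF mean per-SNP instrument-strength F statistic.
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnps = "integer", intercept = "numeric",
                 interceptSE = "numeric", interceptPval = "numeric",
                 Q = "numeric", Qdf = "numeric", Qpval = "numeric",
                 meanF = "numeric"),
  prototype(intercept = NA_real_, interceptSE = NA_real_,
            interceptPval = NA_real_, Q = NA_real_, Qdf = NA_real_,
            Qpval = NA_real_, meanF = NA_real_))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("wald", "ivw_fe", "ivw_mre", "egger",
                            "weighted_median"))
    msg <- c(msg, "unknown method")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the estimate")
  if (is.finite(object@Q) && object@Q < 0) msg <- c(msg, "Q must be >= 0")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (object@method %in% c("egger", "weighted_median") && object@nSnps < 3L)
    msg <- c(msg, "egger and weighted_median need >= 3 instruments")
  if (length(msg)) msg else TRUE
})

#' MVMREstimate: multivariable MR direct-effect estimates
#'
#' @slot exposureNames character vector of exposure labels.
#' @slot betas,ses,ciLows,ciHighs,pvals per-exposure direct effects and
#'   inference.
#' @slot nSnps number of instruments.
#' @slot conditionalF per-exposure conditional instrument-strength F.
#' @slot QA,QAdf,QApval multivariable heterogeneity statistic.
#' @export
setClass("MVMREstimate",
  representation(exposureNames = "character", betas = "numeric",
                 ses = "numeric", ciLows = "numeric", ciHighs = "numeric",
                 pvals = "numeric", nSnps = "integer",
                 conditionalF = "numeric", QA = "numeric", QAdf = "numeric",
                 QApval = "numeric"))

setValidity("MVMREstimate", function(object) {
  msg <- character()
  K <- length(object@betas)
  if (K < 2L) msg <- c(msg, "MVMR requires >= 2 exposures")
  if (length(object@exposureNames) != K || length(object@ses) != K ||
      length(object@pvals) != K)
    msg <- c(msg, "per-exposure slots must have equal length")
  if (is.finite(object@QA) && object@QA < 0) msg <- c(msg, "Q_A must be >= 0")
  if (is.finite(object@QAdf) && object@QAdf != object@nSnps - K)
    msg <- c(msg, "Q_A df must equal n_snps - K")
  if (length(msg)) msg else TRUE
})

#' SteigerResult: per-SNP directionality diagnostics
#'
#' @slot table data.frame with columns \code{snp_id}, \code{r2_exposure},
#'   \code{r2_outcome}, \code{direction_correct}, \code{steiger_pval}.
#' @slot retainedSnps ids of SNPs kept after filtering.
#' @export
setClass("SteigerResult",
  representation(table = "data.frame", retainedSnps = "character"))

setValidity("SteigerResult", function(object) {
  t <- object@table
  if (nrow(t) && (any(t$r2_exposure < 0 | t$r2_exposure > 1) ||
                  any(t$r2_outcome < 0 | t$r2_outcome > 1)))
    return("r-squared values must lie in [0, 1]")
  TRUE
})

#' OutlierReport: per-SNP heterogeneity decomposition
#'
#' @slot method \code{"radial"} or \code{"presso"}.
#' @slot perSnp data.frame with columns \code{snp_id}, \code{ratio},
#'   \code{weight}, \code{q_contribution}, \code{outlier_pval},
#'   \code{flagged}.
#' @slot globalPval global heterogeneity/pleiotropy test p-value
#'   (NA for radial).
#' @slot distortionPval PRESSO distortion-test p-value (NA when no outlier
#'   was flagged).
#' @slot estimateOriginal,estimateCorrected IVW (multiplicative random
#'   effects) estimates before and after outlier removal.
#' @export
setClass("OutlierReport",
  representation(method = "character", perSnp = "data.frame",
                 globalPval = "numeric", distortionPval = "numeric",
                 estimateOriginal = "MREstimate",
                 estimateCorrected = "MREstimate"))

setValidity("OutlierReport", function(object) {
  if (!object@method %in% c("radial", "presso")) return("unknown method")
  TRUE
})

#' ClusterAssignment: mixture-model clustering of ratio estimates
#'
#' @slot K number of non-null substantive clusters selected.
#' @slot assignments data.frame with columns \code{snp_id}, \code{label}
#'   (\code{"cluster_k"}, \code{"null"}, \code{"junk"} or
#'   \code{"unassigned"}), \code{probability}.
#' @slot probabilities L x (K + 2) matrix of conditional assignment
#'   probabilities (columns: clusters, null, junk).
#' @slot clusters per-cluster summary: label, mean slope, SE, size, and the
#'   IVW estimate over assigned members.
#' @slot logLik,criterion fitted log-likelihood and the penalized selection
#'   criterion of the chosen K.
#' @slot seed RNG seed used for the EM restarts.
#' @export
setClass("ClusterAssignment",
  representation(K = "integer", assignments = "data.frame",
                 probabilities = "matrix", clusters = "data.frame",
                 logLik = "numeric", criterion = "numeric", seed = "integer"))

setValidity("ClusterAssignment", function(object) {
  p <- object@probabilities
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-6))
    return("assignment probabilities must sum to 1 per SNP")
  TRUE
})

#' MediationResult: product- and difference-method mediation estimates
#'
#' All effect slots are length-2 numeric vectors \code{c(estimate, se)};
#' the indirect effects and the proportion mediated additionally carry
#' 95\% confidence limits and p-values in their own slots.
#'
#' @slot totalEffect univariable MR exposure-on-outcome effect.
#' @slot directEffect MVMR direct exposure-on-outcome effect.
#' @slot exposureMediator univariable MR exposure-on-mediator effect.
#' @slot mediatorDirect MVMR direct mediator-on-outcome effect.
#' @slot indirectProduct,indirectDifference c(estimate, se, ci_low, ci_high,
#'   pval) for the two indirect-effect constructions.
#' @slot proportionMediated c(estimate, ci_low, ci_high).
#' @slot scale \code{"continuous"} or \code{"log_odds"}.
#' @export
setClass("MediationResult",
  representation(totalEffect = "numeric", directEffect = "numeric",
                 exposureMediator = "numeric", mediatorDirect = "numeric",
                 indirectProduct = "numeric", indirectDifference = "numeric",
                 proportionMediated = "numeric", scale = "character"))

setValidity("MediationResult", function(object) {
  msg <- character()
  if (!object@scale %in% c("continuous", "log_odds"))
    msg <- c(msg, "scale must be 'continuous' or 'log_odds'")
  ip <- object@indirectProduct
  if (abs(ip[1] - object@exposureMediator[1] * object@mediatorDirect[1]) >
      1e-12 * max(1, abs(ip[1])))
    msg <- c(msg, "indirect product must equal the product of its terms")
  id <- object@indirectDifference
  if (abs(id[1] - (object@totalEffect[1] - object@directEffect[1])) >
      1e-12 * max(1, abs(id[1])))
    msg <- c(msg, "indirect difference must equal total minus direct")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the summary-statistic simulator
#'
#' Encodes an exposure -> mediator -> outcome causal diagram with a direct
#' exposure -> outcome path, SNP-level horizontal pleiotropy, planted
#' heterogeneity outliers and optional mechanism clusters. See
#' \code{\link{generateDataset}} for the generative model.
#'
#' @slot seed master RNG seed; per-trait child seeds are derived from it.
#' @slot nSnps number of independent SNPs.
#' @slot mafRange c(low, high) bounds of the uniform MAF distribution.
#' @slot nExposure,nMediator,nOutcome GWAS sample sizes (non-overlapping).
#' @slot gammaMean,gammaSD mean and SD of true SNP-on-exposure effects
#'   (a nonzero mean emulates instruments of comparable strength coded on
#'   the trait-increasing allele).
#' @slot deltaSD SD of direct SNP-on-mediator effects (the mediator's own
#'   instruments; 0 disables them).
#' @slot alpha true exposure-on-mediator effect (SD units).
#' @slot betaMed true mediator-on-outcome effect (log-odds per SD when the
#'   outcome is binary).
#' @slot betaDirect true direct exposure-on-outcome effect.
#' @slot pleiotropyMean,pleiotropySD direct SNP-on-outcome effect
#'   distribution (directional when the mean is nonzero).
#' @slot pleiotropyFraction fraction of SNPs receiving a pleiotropic effect.
#' @slot outlierFraction,outlierEffect fraction of SNPs whose outcome effect
#'   is shifted by \code{outlierEffect} (planted heterogeneity outliers).
#' @slot clusterSpec optional list of \code{c(proportion, slope)} pairs;
#'   when non-empty it overrides the mediation model and plants distinct
#'   causal mechanisms, the remaining SNPs being null.
#' @slot outcomeType \code{"continuous"} or \code{"binary"}.
#' @slot caseFraction case fraction of the binary outcome GWAS.
#' @slot orientGamma when TRUE, SNP-on-exposure effects are drawn
#'   half-normal (all positive), mimicking instruments coded on the
#'   trait-increasing allele.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nSnps = "integer", mafRange = "numeric",
                 nExposure = "numeric", nMediator = "numeric",
                 nOutcome = "numeric", gammaMean = "numeric",
                 gammaSD = "numeric",
                 deltaSD = "numeric", alpha = "numeric", betaMed = "numeric",
                 betaDirect = "numeric", pleiotropyMean = "numeric",
                 pleiotropySD = "numeric", pleiotropyFraction = "numeric",
                 outlierFraction = "numeric", outlierEffect = "numeric",
                 clusterSpec = "list", outcomeType = "character",
                 caseFraction = "numeric", orientGamma = "logical"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  mr <- object@mafRange
  if (length(mr) != 2 || !(0 < mr[1] && mr[1] <= mr[2] && mr[2] < 0.5))
    msg <- c(msg, "mafRange must satisfy 0 < low <= high < 0.5")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (object@outlierFraction < 0 || object@outlierFraction >= 1)
    msg <- c(msg, "outlierFraction must lie in [0, 1)")
  if (object@pleiotropyFraction < 0 || object@pleiotropyFraction > 1)
    msg <- c(msg, "pleiotropyFraction must lie in [0, 1]")
  if (length(object@clusterSpec)) {
    props <- vapply(object@clusterSpec, `[`, numeric(1), 1L)
    if (any(props <= 0) || sum(props) > 1)
      msg <- c(msg, "cluster proportions must be positive and sum to <= 1")
  }
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be 'continuous' or 'binary'")
  if (object@outcomeType == "binary" &&
      (object@caseFraction <= 0 || object@caseFraction >= 1))
    msg <- c(msg, "caseFraction must lie in (0, 1) for binary outcomes")
  if (object@seed < 0L) msg <- c(msg, "seed must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SimulatedTruth: the estimands behind a simulated dataset
#'
#' @slot snpIds SNP identifiers.
#' @slot maf true minor-allele frequencies.
#' @slot gamma true SNP-on-exposure effects.
#' @slot deltaM true direct SNP-on-mediator effects.
#' @slot thetaY true direct SNP-on-outcome effects (pleiotropy plus
#'   planted outlier shifts).
#' @slot alpha,betaMed,betaDirect structural coefficients.
#' @slot totalEffect betaDirect + alpha * betaMed.
#' @slot proportionMediated alpha * betaMed / totalEffect.
#' @slot outlierIds ids of planted heterogeneity outliers.
#' @slot clusterLabels per-SNP mechanism labels (empty unless a cluster
#'   specification was used).
#' @export
setClass("SimulatedTruth",
  representation(snpIds = "character", maf = "numeric", gamma = "numeric",
                 deltaM = "numeric", thetaY = "numeric", alpha = "numeric",
                 betaMed = "numeric", betaDirect = "numeric",
                 totalEffect = "numeric", proportionMediated = "numeric",
                 outlierIds = "character", clusterLabels = "character"))

setValidity("SimulatedTruth", function(object) {
  tot <- object@betaDirect + object@alpha * object@betaMed
  if (abs(object@totalEffect - tot) > 1e-12 * max(1, abs(tot)))
    return("totalEffect must equal betaDirect + alpha * betaMed")
  TRUE
})

#' AnalysisPlan: an ordered multi-step analysis specification
#'
#' @slot steps list of step descriptions (\code{step_id}, \code{analysis},
#'   trait references and options).
#' @slot global list of global settings (\code{seed}, \code{output_dir},
#'   \code{ivw_mode}, \code{palindrome_window}, \code{p_threshold},
#'   \code{prob_threshold}, optional \code{synthetic} preset).
#' @export
setClass("AnalysisPlan",
  representation(steps = "list", global = "list"))
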