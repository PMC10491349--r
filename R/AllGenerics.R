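## Generics, accessors and show methods.

#' Causal-effect estimate
#'
#' Accessors for fitted MR objects: point estimate, standard error, 95\%
#' confidence limits, two-sided p-value and instrument count. For
#' \linkS4class{MVMREstimate} objects they return named per-exposure
#' vectors (or a two-column matrix for \code{mrCI}).
#'
#' @param object an \linkS4class{MREstimate} or \linkS4class{MVMREstimate}.
#' @return numeric scalar/vector (matrix for \code{mrCI} on MVMR fits).
#' @aliases mrBeta mrSE mrCI mrPval nSnps
#' @export
setGeneric("mrBeta", function(object) standardGeneric("mrBeta"))

#' @rdname mrBeta
#' @export
setGeneric("mrSE", function(object) standardGeneric("mrSE"))

#' @rdname mrBeta
#' @export
setGeneric("mrCI", function(object) standardGeneric("mrCI"))

#' @rdname mrBeta
#' @export
setGeneric("mrPval", function(object) standardGeneric("mrPval"))

#' @rdname mrBeta
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))

#' Heterogeneity statistic of a fitted MR object
#'
#' @param object an \linkS4class{MREstimate} or \linkS4class{MVMREstimate}.
#' @return named list with elements \code{Q} (for MVMR fits, the adapted
#'   statistic Q_A), \code{df} and \code{pval}.
#' @export
setGeneric("heterogeneityQ", function(object) standardGeneric("heterogeneityQ"))

#' SNP identifiers of a container
#'
#' @param object a \linkS4class{GwasSummaryStats} or
#'   \linkS4class{HarmonizedMRData}.
#' @return character vector of variant ids.
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' Write an estimate or report to disk
#'
#' Writes a tab-separated table with a fixed, documented column order plus
#' a JSON sidecar (\code{<path>.json}) carrying full numeric precision and
#' run metadata (package version and, when recorded on the object, the
#' seed and configuration hash).
#'
#' @param object a fitted estimate/report object or a data.frame.
#' @param path output TSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return invisibly, the path written.
#' @export
setGeneric("writeResults", function(object, path) standardGeneric("writeResults"))

## ---- accessors ----

#' @rdname mrBeta
setMethod("mrBeta", "MREstimate", function(object) object@beta)
#' @rdname mrBeta
setMethod("mrSE", "MREstimate", function(object) object@se)
#' @rdname mrBeta
setMethod("mrCI", "MREstimate", function(object)
  c(low = object@ciLow, high = object@ciHigh))
#' @rdname mrBeta
setMethod("mrPval", "MREstimate", function(object) object@pval)
#' @rdname mrBeta
setMethod("nSnps", "MREstimate", function(object) object@nSnps)

#' @rdname mrBeta
setMethod("mrBeta", "MVMREstimate", function(object)
  stats::setNames(object@betas, object@exposureNames))
#' @rdname mrBeta
setMethod("mrSE", "MVMREstimate", function(object)
  stats::setNames(object@ses, object@exposureNames))
#' @rdname mrBeta
setMethod("mrCI", "MVMREstimate", function(object) {
  m <- cbind(low = object@ciLows, high = object@ciHighs)
  rownames(m) <- object@exposureNames
  m
})
#' @rdname mrBeta
setMethod("mrPval", "MVMREstimate", function(object)
  stats::setNames(object@pvals, object@exposureNames))
#' @rdname mrBeta
setMethod("nSnps", "MVMREstimate", function(object) object@nSnps)
#' @rdname mrBeta
setMethod("nSnps", "HarmonizedMRData", function(object)
  length(object@snpIds))

setMethod("heterogeneityQ", "MREstimate", function(object)
  list(Q = object@Q, df = object@Qdf, pval = object@Qpval))
setMethod("heterogeneityQ", "MVMREstimate", function(object)
  list(Q = object@QA, df = object@QAdf, pval = object@QApval))

setMethod("snpIds", "GwasSummaryStats", function(object) object@data$snp_id)
setMethod("snpIds", "HarmonizedMRData", function(object) object@snpIds)

#' Trait name and type of a summary-statistics container
#'
#' @param object a \linkS4class{GwasSummaryStats}.
#' @return single character.
#' @aliases traitName traitType
#' @export
setGeneric("traitName", function(object) standardGeneric("traitName"))
#' @rdname traitName
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))
#' @rdname traitName
setMethod("traitName", "GwasSummaryStats", function(object) object@traitName)
#' @rdname traitName
setMethod("traitType", "GwasSummaryStats", function(object) object@traitType)

#' Per-SNP association table of a container
#'
#' @param object a \linkS4class{GwasSummaryStats}.
#' @return data.frame of per-variant associations.
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))
#' @rdname associations
setMethod("associations", "GwasSummaryStats", function(object) object@data)

#' Records dropped during validation or harmonization
#'
#' @param object a \linkS4class{GwasSummaryStats} or
#'   \linkS4class{HarmonizedMRData}.
#' @return data.frame with columns \code{snp_id} and \code{reason}.
#' @export
setGeneric("droppedRecords", function(object) standardGeneric("droppedRecords"))
#' @rdname droppedRecords
setMethod("droppedRecords", "GwasSummaryStats", function(object) object@dropLog)
#' @rdname droppedRecords
setMethod("droppedRecords", "HarmonizedMRData", function(object) object@dropped)

#' Exposure and outcome effect matrices of harmonized data
#'
#' @param object a \linkS4class{HarmonizedMRData}.
#' @return numeric matrix (exposures) or vector (outcome).
#' @aliases betaExposure seExposure betaOutcome seOutcome
#' @export
setGeneric("betaExposure", function(object) standardGeneric("betaExposure"))
#' @rdname betaExposure
#' @export
setGeneric("seExposure", function(object) standardGeneric("seExposure"))
#' @rdname betaExposure
#' @export
setGeneric("betaOutcome", function(object) standardGeneric("betaOutcome"))
#' @rdname betaExposure
#' @export
setGeneric("seOutcome", function(object) standardGeneric("seOutcome"))
#' @rdname betaExposure
setMethod("betaExposure", "HarmonizedMRData", function(object) object@betaX)
#' @rdname betaExposure
setMethod("seExposure", "HarmonizedMRData", function(object) object@seX)
#' @rdname betaExposure
setMethod("betaOutcome", "HarmonizedMRData", function(object) object@betaY)
#' @rdname betaExposure
setMethod("seOutcome", "HarmonizedMRData", function(object) object@seY)

## ---- show methods ----

setMethod("show", "GwasSummaryStats", function(object) {
  cat("GwasSummaryStats:", object@traitName, sprintf("(%s)\n", object@traitType))
  cat("  ", nrow(object@data), "variants;", nrow(object@dropLog),
      "dropped during validation\n")
})

setMethod("show", "HarmonizedMRData", function(object) {
  cat("HarmonizedMRData:", ncol(object@betaX), "exposure(s) ->",
      sprintf("%s outcome\n", object@outcomeType))
  cat("  ", length(object@snpIds), "harmonized SNPs (",
      sum(object@flags$flipped), "allele-flipped,",
      nrow(object@dropped), "dropped )\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@method, object@beta, object@se, object@ciLow,
              object@ciHigh, object@pval))
  cat(sprintf("  %d SNPs; Q = %.2f (df %d, p = %.3g); mean F = %.1f\n",
              object@nSnps, object@Q, as.integer(object@Qdf), object@Qpval,
              object@meanF))
  if (object@method == "egger")
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n", object@intercept,
                object@interceptSE, object@interceptPval))
})

setMethod("show", "MVMREstimate", function(object) {
  cat("MVMREstimate:", object@nSnps, "SNPs,",
      length(object@betas), "exposures\n")
  for (k in seq_along(object@betas))
    cat(sprintf("  %s: beta = %.4f (SE %.4f), p = %.3g, conditional F = %.1f\n",
                object@exposureNames[k], object@betas[k], object@ses[k],
                object@pvals[k], object@conditionalF[k]))
  cat(sprintf("  Q_A = %.2f (df %d, p = %.3g)\n", object@QA,
              as.integer(object@QAdf), object@QApval))
})

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport [%s]: %d / %d SNPs flagged\n", object@method,
              sum(object@perSnp$flagged), nrow(object@perSnp)))
  if (is.finite(object@globalPval))
    cat(sprintf("  global test p = %.3g\n", object@globalPval))
  if (is.finite(object@distortionPval))
    cat(sprintf("  distortion test p = %.3g\n", object@distortionPval))
  cat(sprintf("  original beta %.4f -> corrected %.4f\n",
              object@estimateOriginal@beta, object@estimateCorrected@beta))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: K =", object@K, "substantive cluster(s)\n")
  print(object@clusters, row.names = FALSE)
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (", object@scale, "scale )\n")
  cat(sprintf("  total effect      %8.4f (SE %.4f)\n", object@totalEffect[1],
              object@totalEffect[2]))
  cat(sprintf("  direct effect     %8.4f (SE %.4f)\n", object@directEffect[1],
              object@directEffect[2]))
  cat(sprintf("  indirect (product)    %8.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              object@indirectProduct[1], object@indirectProduct[2],
              object@indirectProduct[3], object@indirectProduct[4]))
  cat(sprintf("  indirect (difference) %8.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              object@indirectDifference[1], object@indirectDifference[2],
              object@indirectDifference[3], object@indirectDifference[4]))
  cat(sprintf("  proportion mediated   %8.4f [%.4f, %.4f]\n",
              object@proportionMediated[1], object@proportionMediated[2],
              object@proportionMediated[3]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSnps, "SNPs, seed", object@seed, "\n")
  cat(sprintf("  alpha = %.3f, betaMed = %.3f, betaDirect = %.4f (total %.4f)\n",
              object@alpha, object@betaMed, object@betaDirect,
              object@betaDirect + object@alpha * object@betaMed))
  cat(sprintf("  outcome: %s; n = %g / %g / %g\n", object@outcomeType,
              object@nExposure, object@nMediator, object@nOutcome))
})

setMethod("show", "SimulatedTruth", function(object) {
  cat(sprintf("SimulatedTruth: total effect %.4f, proportion mediated %.4f\n",
              object@totalEffect, object@proportionMediated))
  cat("  ", length(object@snpIds), "SNPs;", length(object@outlierIds),
      "planted outliers\n")
})

setMethod("show", "AnalysisPlan", function(object) {
  cat("AnalysisPlan:", length(object@steps), "step(s), seed",
      object@global$seed, "\n")
  for (s in object@steps)
    cat("  -", s$step_id, sprintf("[%s]\n", s$analysis))
})
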