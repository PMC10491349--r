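## TSV + JSON-sidecar export of estimates and reports.

writeTSVWithSidecar <- function(tab, fullList, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  meta <- list(package = "mrmediate",
               version = as.character(utils::packageVersion("mrmediate")))
  jsonlite::write_json(c(fullList, list(metadata = meta)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

mrEstimateRow <- function(object) {
  data.frame(method = object@method, beta = object@beta, se = object@se,
             ci_low = object@ciLow, ci_high = object@ciHigh,
             pval = object@pval, n_snps = object@nSnps, Q = object@Q,
             Q_pval = object@Qpval, stringsAsFactors = FALSE)
}

#' @describeIn writeResults one row: method, beta, se, ci_low, ci_high,
#'   pval, n_snps, Q, Q_pval (Egger intercept terms in the sidecar).
setMethod("writeResults", "MREstimate", function(object, path) {
  full <- list(method = object@method, beta = object@beta, se = object@se,
               ci_low = object@ciLow, ci_high = object@ciHigh,
               pval = object@pval, n_snps = object@nSnps,
               intercept = object@intercept,
               intercept_se = object@interceptSE,
               intercept_pval = object@interceptPval,
               Q = object@Q, Q_df = object@Qdf, Q_pval = object@Qpval,
               mean_F = object@meanF)
  writeTSVWithSidecar(mrEstimateRow(object), full, path)
})

#' @describeIn writeResults one row per exposure: exposure, beta, se,
#'   ci_low, ci_high, pval, conditional_F, n_snps, Q_A, Q_A_pval.
setMethod("writeResults", "MVMREstimate", function(object, path) {
  tab <- data.frame(exposure = object@exposureNames, beta = object@betas,
                    se = object@ses, ci_low = object@ciLows,
                    ci_high = object@ciHighs, pval = object@pvals,
                    conditional_F = object@conditionalF,
                    n_snps = object@nSnps, Q_A = object@QA,
                    Q_A_pval = object@QApval, stringsAsFactors = FALSE)
  full <- list(exposures = object@exposureNames, betas = object@betas,
               ses = object@ses, ci_lows = object@ciLows,
               ci_highs = object@ciHighs, pvals = object@pvals,
               conditional_F = object@conditionalF, n_snps = object@nSnps,
               Q_A = object@QA, Q_A_df = object@QAdf,
               Q_A_pval = object@QApval)
  writeTSVWithSidecar(tab, full, path)
})

#' @describeIn writeResults one row per method (product, difference) plus
#'   the proportion mediated; the four input effects are echoed in the
#'   sidecar for auditability.
setMethod("writeResults", "MediationResult", function(object, path) {
  tab <- data.frame(
    method = c("product", "difference"),
    indirect = c(object@indirectProduct[1], object@indirectDifference[1]),
    se = c(object@indirectProduct[2], object@indirectDifference[2]),
    ci_low = c(object@indirectProduct[3], object@indirectDifference[3]),
    ci_high = c(object@indirectProduct[4], object@indirectDifference[4]),
    pval = c(object@indirectProduct[5], object@indirectDifference[5]),
    proportion_mediated = c(object@proportionMediated[1], NA),
    proportion_ci_low = c(object@proportionMediated[2], NA),
    proportion_ci_high = c(object@proportionMediated[3], NA),
    scale = object@scale, stringsAsFactors = FALSE)
  full <- list(total_effect = object@totalEffect,
               direct_effect = object@directEffect,
               exposure_mediator = object@exposureMediator,
               mediator_direct = object@mediatorDirect,
               indirect_product = object@indirectProduct,
               indirect_difference = object@indirectDifference,
               proportion_mediated = object@proportionMediated,
               scale = object@scale)
  writeTSVWithSidecar(tab, full, path)
})

#' @describeIn writeResults the per-SNP table (ratio, weight,
#'   Q contribution, outlier p, flag) with the global/distortion p-values
#'   and both estimates in the sidecar.
setMethod("writeResults", "OutlierReport", function(object, path) {
  full <- list(method = object@method, global_pval = object@globalPval,
               distortion_pval = object@distortionPval,
               estimate_original = mrEstimateRow(object@estimateOriginal),
               estimate_corrected = mrEstimateRow(object@estimateCorrected),
               per_snp = object@perSnp)
  writeTSVWithSidecar(object@perSnp, full, path)
})

#' @describeIn writeResults the per-SNP assignment table (label and
#'   probability, scatter-plot ready) with per-cluster summaries in the
#'   sidecar.
setMethod("writeResults", "ClusterAssignment", function(object, path) {
  full <- list(K = object@K, assignments = object@assignments,
               clusters = object@clusters, log_lik = object@logLik,
               criterion = object@criterion, seed = object@seed)
  writeTSVWithSidecar(object@assignments, full, path)
})

#' @describeIn writeResults the Steiger per-SNP table.
setMethod("writeResults", "SteigerResult", function(object, path) {
  full <- list(table = object@table, retained = object@retainedSnps)
  writeTSVWithSidecar(object@table, full, path)
})

#' @describeIn writeResults a plain table (header-only TSV when empty).
setMethod("writeResults", "data.frame", function(object, path) {
  writeTSVWithSidecar(object, list(table = object), path)
})
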