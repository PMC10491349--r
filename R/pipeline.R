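## Pipeline orchestration: analysis plans, config validation, execution.

PLAN_DEFAULTS <- list(seed = 1L, output_dir = NULL, ivw_mode = "mre",
                      palindrome_window = 0.08, p_threshold = 5e-8,
                      prune_window = 1e7, prob_threshold = 0.9,
                      n_boot = 1000, n_sim = 1000, max_k = 5,
                      synthetic = NULL)

KNOWN_ANALYSES <- c("mr", "mvmr", "radial", "presso", "cluster", "steiger",
                    "mediation")

#' Construct an AnalysisPlan
#'
#' @param steps list of step descriptions; each needs \code{step_id} and
#'   \code{analysis} plus the trait references the analysis requires
#'   (\code{exposure}/\code{exposures}, \code{outcome}, \code{mediator},
#'   or for mediation the \code{total_step}, \code{em_step} and
#'   \code{mvmr_step} it combines).
#' @param global named list of global settings; unset keys take the
#'   documented defaults (\code{ivw_mode} "mre", \code{p_threshold} 5e-8,
#'   \code{prob_threshold} 0.9, \code{palindrome_window} 0.08, seed 1).
#' @return a validated \linkS4class{AnalysisPlan}.
#' @export
analysisPlan <- function(steps, global = list()) {
  global <- utils::modifyList(PLAN_DEFAULTS, global)
  plan <- new("AnalysisPlan", steps = steps, global = global)
  violations <- validatePlan(plan)
  if (length(violations))
    stop("invalid analysis plan:\n  - ",
         paste(violations, collapse = "\n  - "))
  plan
}

#' Validate an analysis plan, returning all violations
#'
#' Checks the whole plan and returns every violation found (not just the
#' first): duplicate or missing step ids, unknown analysis types, missing
#' trait references, mediation steps referencing unknown or later steps,
#' and invalid global settings.
#'
#' @param plan an \linkS4class{AnalysisPlan}.
#' @return character vector of violations (empty when valid).
#' @export
validatePlan <- function(plan) {
  v <- character(0)
  g <- plan@global
  if (!is.numeric(g$seed) || length(g$seed) != 1 || is.na(g$seed) ||
      g$seed < 0 || g$seed != floor(g$seed))
    v <- c(v, "global seed must be a non-negative integer")
  if (!g$ivw_mode %in% c("mre", "fe"))
    v <- c(v, "ivw_mode must be 'mre' or 'fe'")
  if (!is.numeric(g$p_threshold) || g$p_threshold <= 0 || g$p_threshold > 1)
    v <- c(v, "p_threshold must lie in (0, 1]")
  if (!is.numeric(g$prob_threshold) || g$prob_threshold <= 0 ||
      g$prob_threshold > 1)
    v <- c(v, "prob_threshold must lie in (0, 1]")

  ids <- vapply(plan@steps, function(s)
    if (is.null(s$step_id)) NA_character_ else as.character(s$step_id), "")
  if (anyNA(ids)) v <- c(v, "every step needs a step_id")
  dup <- unique(ids[duplicated(ids) & !is.na(ids)])
  if (length(dup)) v <- c(v, paste0("duplicate step_id: ", dup))

  for (i in seq_along(plan@steps)) {
    s <- plan@steps[[i]]
    id <- if (is.null(s$step_id)) paste0("step ", i) else s$step_id
    if (is.null(s$analysis) || !s$analysis %in% KNOWN_ANALYSES) {
      v <- c(v, paste0(id, ": unknown analysis '",
                       if (is.null(s$analysis)) "" else s$analysis, "'"))
      next
    }
    if (s$analysis == "mediation") {
      for (ref in c("total_step", "em_step", "mvmr_step")) {
        r <- s[[ref]]
        if (is.null(r)) {
          v <- c(v, paste0(id, ": mediation needs ", ref))
        } else {
          j <- match(r, ids)
          if (is.na(j)) v <- c(v, paste0(id, ": ", ref, " references ",
                                         "unknown step '", r, "'"))
          else if (j >= i) v <- c(v, paste0(id, ": ", ref,
                                            " must reference an earlier step"))
        }
      }
    } else if (s$analysis == "mvmr") {
      if (length(s$exposures) < 2)
        v <- c(v, paste0(id, ": mvmr needs >= 2 exposures"))
      if (is.null(s$outcome)) v <- c(v, paste0(id, ": missing outcome"))
    } else {
      if (is.null(s$exposure)) v <- c(v, paste0(id, ": missing exposure"))
      if (is.null(s$outcome)) v <- c(v, paste0(id, ": missing outcome"))
    }
  }
  v
}

#' Read and validate an analysis plan from a YAML config file
#'
#' The file must contain a \code{steps} list and may contain a
#' \code{global} mapping; unset global keys take the documented defaults.
#' All violations are reported together, not first-failure.
#'
#' @param path YAML config file.
#' @return a validated \linkS4class{AnalysisPlan}.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("unparseable config ", path, ": ", conditionMessage(e)))
  if (is.null(cfg$steps)) stop("config must define 'steps'")
  global <- if (is.null(cfg$global)) list() else cfg$global
  analysisPlan(cfg$steps, global)
}

resolveTraits <- function(plan, inputs) {
  if (!is.null(plan@global$synthetic)) {
    sim <- generateDataset(mediationScenario(plan@global$synthetic,
                                             seed = plan@global$seed))
    inputs <- utils::modifyList(
      list(exposure = sim$exposure, mediator = sim$mediator,
           outcome = sim$outcome), as.list(inputs))
  }
  lapply(inputs, function(x) {
    if (is(x, "GwasSummaryStats")) x
    else if (is.character(x) && length(x) == 1) readSummaryStats(x)
    else stop("inputs must be GwasSummaryStats objects or file paths")
  })
}

#' Execute an analysis plan
#'
#' Runs the plan's steps in order over the given traits, reusing
#' harmonized instrument sets within a step, and writes one TSV + JSON
#' sidecar per step plus a consolidated report (JSON and human-readable
#' text) when \code{output_dir} is set. Stochastic steps (weighted-median
#' bootstrap, PRESSO simulations, clustering restarts) consume seeds
#' derived deterministically from the global seed, so identical plans
#' reproduce identical outputs byte for byte. A step that hard-errors is
#' recorded with status \code{"error"} and the run raises at the end.
#'
#' @param plan an \linkS4class{AnalysisPlan}.
#' @param inputs named list mapping trait names to
#'   \linkS4class{GwasSummaryStats} objects or file paths; may be empty
#'   when the plan names a \code{synthetic} preset.
#' @return the consolidated report, an invisible named list with one
#'   entry per step (\code{status}, \code{result}) plus \code{global}.
#' @export
runPipeline <- function(plan, inputs = list()) {
  stopifnot(is(plan, "AnalysisPlan"))
  violations <- validatePlan(plan)
  if (length(violations))
    stop("invalid analysis plan:\n  - ",
         paste(violations, collapse = "\n  - "))
  traits <- resolveTraits(plan, inputs)

  needed <- unique(unlist(lapply(plan@steps, function(s)
    c(s$exposure, s$exposures, s$mediator, s$outcome))))
  missing_traits <- setdiff(needed, names(traits))
  if (length(missing_traits))
    stop("plan references undefined trait(s): ",
         paste(missing_traits, collapse = ", "))

  g <- plan@global
  outdir <- g$output_dir
  results <- list()
  errors <- character(0)

  instruments <- function(name) selectInstruments(traits[[name]],
                                                  g$p_threshold,
                                                  g$prune_window)
  harmon <- function(expos, outcome)
    harmonizeTraits(expos, traits[[outcome]], g$palindrome_window)

  for (i in seq_along(plan@steps)) {
    s <- plan@steps[[i]]
    stepSeed <- deriveSeed(g$seed, i)
    res <- tryCatch({
      switch(s$analysis,
        mr = {
          h <- harmon(instruments(s$exposure), s$outcome)
          out <- list(ivw = mrIVW(h, mode = g$ivw_mode),
                      wald = waldRatios(h))
          if (nSnps(h) >= 3) {
            out$egger <- mrEgger(h)
            out$weighted_median <- mrWeightedMedian(h, nBoot = g$n_boot,
                                                    seed = stepSeed)
          }
          out
        },
        mvmr = {
          ids <- unique(unlist(lapply(s$exposures, function(e)
            snpIds(instruments(e)))))
          expos <- lapply(s$exposures, function(e)
            subsetStats(traits[[e]], ids))
          list(mvmr = mvmrIVW(harmon(expos, s$outcome)))
        },
        radial = {
          h <- harmon(instruments(s$exposure), s$outcome)
          list(radial = radialOutliers(h))
        },
        presso = {
          h <- harmon(instruments(s$exposure), s$outcome)
          list(presso = mrPresso(h, nSim = g$n_sim, seed = stepSeed))
        },
        cluster = {
          h <- harmon(instruments(s$exposure), s$outcome)
          list(cluster = clusterRatios(h, maxK = g$max_k,
                                       probThreshold = g$prob_threshold,
                                       seed = stepSeed))
        },
        steiger = {
          h <- harmon(instruments(s$exposure), s$outcome)
          sf <- steigerFilter(h)
          list(steiger = sf$result)
        },
        mediation = {
          tot <- results[[s$total_step]]$result$ivw
          em <- results[[s$em_step]]$result$ivw
          mv <- results[[s$mvmr_step]]$result$mvmr
          scale <- if (traits[[s$outcome %||% "outcome"]]@traitType ==
                       "binary") "log_odds" else "continuous"
          list(mediation = mediationResult(
            total = c(tot@beta, tot@se),
            direct = c(mv@betas[1], mv@ses[1]),
            exposureMediator = c(em@beta, em@se),
            mediatorDirect = c(mv@betas[2], mv@ses[2]), scale = scale))
        })
    }, error = function(e) structure(conditionMessage(e), class = "stepError"))
    if (inherits(res, "stepError")) {
      errors <- c(errors, paste0(s$step_id, ": ", res))
      results[[s$step_id]] <- list(status = "error", result = as.character(res))
    } else {
      results[[s$step_id]] <- list(status = "ok", result = res)
      if (!is.null(outdir)) {
        for (nm in names(res))
          writeResults(res[[nm]],
                       file.path(outdir, paste0(s$step_id, "_", nm, ".tsv")))
      }
    }
  }
  report <- list(global = g, steps = results)
  if (!is.null(outdir)) writeReport(report, outdir)
  if (length(errors))
    stop("pipeline step(s) failed:\n  - ", paste(errors, collapse = "\n  - "))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## serialize a step result object into plain lists for the JSON report
reportEntry <- function(x) {
  if (is(x, "MREstimate"))
    list(method = x@method, beta = x@beta, se = x@se, ci = c(x@ciLow, x@ciHigh),
         pval = x@pval, n_snps = x@nSnps, Q = x@Q, Q_pval = x@Qpval,
         intercept = x@intercept, intercept_pval = x@interceptPval,
         mean_F = x@meanF)
  else if (is(x, "MVMREstimate"))
    list(exposures = x@exposureNames, betas = x@betas, ses = x@ses,
         pvals = x@pvals, conditional_F = x@conditionalF, Q_A = x@QA,
         Q_A_pval = x@QApval, n_snps = x@nSnps)
  else if (is(x, "OutlierReport"))
    list(method = x@method, n_flagged = sum(x@perSnp$flagged),
         flagged = x@perSnp$snp_id[x@perSnp$flagged],
         global_pval = x@globalPval, distortion_pval = x@distortionPval,
         beta_original = x@estimateOriginal@beta,
         beta_corrected = x@estimateCorrected@beta)
  else if (is(x, "ClusterAssignment"))
    list(K = x@K, clusters = x@clusters, assignments = x@assignments)
  else if (is(x, "SteigerResult"))
    list(n_retained = length(x@retainedSnps),
         n_removed = nrow(x@table) - length(x@retainedSnps))
  else if (is(x, "MediationResult"))
    list(total = x@totalEffect, direct = x@directEffect,
         indirect_product = x@indirectProduct,
         indirect_difference = x@indirectDifference,
         proportion_mediated = x@proportionMediated, scale = x@scale)
  else x
}

writeReport <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ## output_dir is machine-specific; keep it out of the report so that
  ## identical plans give byte-identical reports wherever they run
  g <- report$global
  g$output_dir <- NULL
  json <- list(global = g[!vapply(g, is.null, logical(1))],
               steps = lapply(report$steps, function(s)
                 list(status = s$status,
                      result = if (s$status == "ok")
                        lapply(s$result, reportEntry) else s$result)))
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  txt <- c("mrmediate pipeline report",
           paste0("seed: ", report$global$seed), "")
  for (id in names(report$steps)) {
    s <- report$steps[[id]]
    txt <- c(txt, paste0("[", id, "] status: ", s$status))
    if (s$status == "ok") {
      for (nm in names(s$result)) {
        x <- s$result[[nm]]
        line <- if (is(x, "MREstimate"))
          sprintf("  %s: beta %.4f (SE %.4f), p %.3g, Q %.2f, mean F %.1f",
                  x@method, x@beta, x@se, x@pval, x@Q, x@meanF)
        else if (is(x, "MVMREstimate"))
          paste0("  mvmr: ", paste(sprintf("%s %.4f (SE %.4f)",
                                           x@exposureNames, x@betas,
                                           x@ses), collapse = "; "),
                 sprintf("; Q_A %.2f", x@QA))
        else if (is(x, "OutlierReport"))
          sprintf("  %s: %d flagged, corrected beta %.4f", x@method,
                  sum(x@perSnp$flagged), x@estimateCorrected@beta)
        else if (is(x, "ClusterAssignment"))
          sprintf("  cluster: K = %d", x@K)
        else if (is(x, "MediationResult"))
          sprintf("  mediation: proportion mediated %.3f [%.3f, %.3f]",
                  x@proportionMediated[1], x@proportionMediated[2],
                  x@proportionMediated[3])
        else if (is(x, "SteigerResult"))
          sprintf("  steiger: %d retained", length(x@retainedSnps))
        else paste0("  ", nm)
        txt <- c(txt, line)
      }
    } else txt <- c(txt, paste0("  ", s$result))
  }
  writeLines(txt, file.path(outdir, "report.txt"))
}
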