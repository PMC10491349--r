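## Reading, validation, harmonization and instrument selection of GWAS
## summary statistics.

#' Construct a GwasSummaryStats object from a per-variant table
#'
#' Validates a data.frame of per-SNP associations, dropping rows that
#' violate the per-variant invariants and recording each drop with a
#' reason. Rows with a p-value inconsistent with |beta/se| under the
#' two-sided normal approximation (by more than a factor of 10) trigger a
#' warning but are retained.
#'
#' @param traitName trait label.
#' @param traitType \code{"continuous"} or \code{"binary"} (binary betas
#'   are interpreted as log-odds).
#' @param data data.frame with columns \code{snp_id},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}, \code{pval}, \code{n} and optionally \code{chrom},
#'   \code{pos}.
#' @return a validated \linkS4class{GwasSummaryStats}.
#' @examples
#' d <- data.frame(snp_id = c("rs1", "rs2"), effect_allele = "A",
#'                 other_allele = "G", eaf = 0.3, beta = c(0.1, -0.2),
#'                 se = 0.02, pval = c(1e-9, 1e-10), n = 1e5)
#' GwasSummaryStats("exposure", "continuous", d)
#' @export
GwasSummaryStats <- function(traitName, traitType = c("continuous", "binary"),
                             data) {
  traitType <- match.arg(traitType)
  data <- as.data.frame(data)
  if (!"chrom" %in% names(data)) data$chrom <- NA_character_
  if (!"pos" %in% names(data)) data$pos <- NA_integer_
  mandatory <- setdiff(SUMMARY_COLUMNS, c("chrom", "pos"))
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])

  reason <- rep(NA_character_, nrow(data))
  mark <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- mark(!data$effect_allele %in% VALID_ALLELES |
                 !data$other_allele %in% VALID_ALLELES, "non_snv_allele")
  reason <- mark(data$effect_allele == data$other_allele, "identical_alleles")
  reason <- mark(!is.finite(data$beta) | !is.finite(data$se) |
                 !is.finite(data$eaf) | !is.finite(data$pval) |
                 !is.finite(data$n), "missing_value")
  reason <- mark(data$se <= 0, "nonpositive_se")
  reason <- mark(data$eaf <= 0 | data$eaf >= 1, "eaf_out_of_range")
  reason <- mark(data$pval <= 0 | data$pval > 1, "pval_out_of_range")
  reason <- mark(data$n <= 0, "nonpositive_n")
  reason <- mark(duplicated(data$snp_id), "duplicate_snp_id")

  keep <- is.na(reason)
  dropLog <- data.frame(snp_id = data$snp_id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  data <- data[keep, SUMMARY_COLUMNS, drop = FALSE]
  rownames(data) <- NULL

  if (nrow(data)) {
    expected <- zPval(data$beta, data$se)
    off <- expected > 0 & (data$pval / expected > 10 |
                           expected / data$pval > 10)
    if (any(off))
      warning(sum(off), " variant(s) in '", traitName,
              "' have p-values inconsistent with |beta/se| by more than ",
              "a factor of 10")
  }
  new("GwasSummaryStats", traitName = as.character(traitName),
      traitType = traitType, data = data, dropLog = dropLog)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a delimited text file (gzip transparently accepted), renames
#' columns through \code{columnMap}, and validates the records through
#' \code{\link{GwasSummaryStats}}. Rows failing validation are dropped
#' with a logged reason (see \code{\link{droppedRecords}}).
#'
#' @param path file path; TSV by default.
#' @param columnMap named character vector mapping the standard field
#'   names (\code{snp_id}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n}, optionally
#'   \code{chrom}, \code{pos}) to the file's column names. Standard names
#'   already present in the file need not be mapped.
#' @param traitType \code{"continuous"} or \code{"binary"}.
#' @param traitName trait label; defaults to the file name.
#' @param delim field delimiter (default tab).
#' @return a \linkS4class{GwasSummaryStats}.
#' @export
readSummaryStats <- function(path, columnMap = NULL,
                             traitType = c("continuous", "binary"),
                             traitName = NULL, delim = "\t") {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = delim, header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  if (!nrow(raw)) stop("empty file: ", path)
  if (!is.null(columnMap)) {
    for (std in names(columnMap)) {
      src <- columnMap[[std]]
      if (!src %in% names(raw))
        stop("mapped column '", src, "' for field '", std,
             "' not present in ", path)
      names(raw)[names(raw) == src] <- std
    }
  }
  mandatory <- setdiff(SUMMARY_COLUMNS, c("chrom", "pos"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(traitName)) traitName <- basename(path)
  GwasSummaryStats(traitName, traitType, raw)
}

#' Select genetic instruments by p-value threshold and positional pruning
#'
#' Retains variants with \code{pval < pThreshold}. When chromosome and
#' position are available, variants are then greedily pruned: in order of
#' increasing p-value (ties broken by snp_id), each kept variant removes
#' all others within \code{pruneWindow} base pairs on the same chromosome.
#' This positional pruning stands in for reference-panel LD clumping,
#' which needs genotype data. Without positions, all threshold-passing
#' variants are kept and a warning notes that pruning was skipped.
#'
#' @param stats a \linkS4class{GwasSummaryStats}.
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @param pruneWindow pruning window in base pairs (default 10 Mb).
#' @return a \linkS4class{GwasSummaryStats} restricted to the selected
#'   instruments.
#' @export
selectInstruments <- function(stats, pThreshold = 5e-8, pruneWindow = 1e7) {
  stopifnot(is(stats, "GwasSummaryStats"))
  d <- stats@data
  if (!nrow(d)) stop("no variants in '", stats@traitName, "'")
  d <- d[d$pval < pThreshold, , drop = FALSE]
  if (!nrow(d))
    stop("no instruments: no variant passes p < ", format(pThreshold),
         " in '", stats@traitName, "'")
  if (all(is.finite(d$pos)) && all(!is.na(d$chrom))) {
    ord <- order(d$pval, d$snp_id)
    d <- d[ord, , drop = FALSE]
    keep <- logical(nrow(d))
    masked <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (masked[i]) next
      keep[i] <- TRUE
      masked <- masked | (d$chrom == d$chrom[i] &
                          abs(d$pos - d$pos[i]) <= pruneWindow)
    }
    d <- d[keep, , drop = FALSE]
  } else {
    warning("positions unavailable for '", stats@traitName,
            "': LD pruning skipped")
  }
  d <- d[order(d$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  new("GwasSummaryStats", traitName = stats@traitName,
      traitType = stats@traitType, data = d, dropLog = stats@dropLog)
}

## Align one trait's records (indexed rows of `d`) to the reference
## effect/other allele coding. Returns list(beta, se, eaf, n, flipped,
## palindromic, drop_reason).
alignToReference <- function(d, refEA, refOA, refEAF, window) {
  ea <- d$effect_allele; oa <- d$other_allele
  beta <- d$beta; eaf <- d$eaf
  flipped <- rep(FALSE, nrow(d))
  reason <- rep(NA_character_, nrow(d))

  same <- ea == refEA & oa == refOA
  swap <- ea == refOA & oa == refEA
  cea <- complementAllele(ea); coa <- complementAllele(oa)
  csame <- !same & !swap & cea == refEA & coa == refOA
  cswap <- !same & !swap & cea == refOA & coa == refEA
  none <- !(same | swap | csame | cswap)
  reason[none] <- "allele_mismatch"

  doflip <- swap | cswap
  beta[doflip] <- -beta[doflip]
  eaf[doflip] <- 1 - eaf[doflip]
  flipped[doflip] <- TRUE

  ## palindromic pairs: letter alignment cannot resolve strand; infer from
  ## allele frequency, requiring both frequencies clearly off 0.5 and on
  ## the same side, otherwise drop.
  pal <- isPalindromic(refEA, refOA) & !none
  if (any(pal)) {
    offRef <- abs(refEAF[pal] - 0.5) > window
    offTrt <- abs(eaf[pal] - 0.5) > window
    sameSide <- sign(refEAF[pal] - 0.5) == sign(eaf[pal] - 0.5)
    ok <- offRef & offTrt & sameSide
    reason[pal][!ok] <- "palindromic_ambiguous"
  }
  list(beta = beta, se = d$se, eaf = eaf, n = d$n, flipped = flipped,
       palindromic = pal & is.na(reason), reason = reason)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Builds the allele-aligned joint dataset used by every estimator. All
#' traits are aligned to the first exposure's effect-allele coding: when a
#' trait codes the swapped (or strand-complement swapped) alleles, its
#' beta is negated and its frequency complemented. Palindromic variants
#' (A/T or C/G) are retained only when the effect-allele frequency of both
#' traits lies outside \code{[0.5 - palindromeWindow, 0.5 +
#' palindromeWindow]} and on the same side of 0.5; otherwise they are
#' dropped with reason \code{"palindromic_ambiguous"}. Variants absent
#' from any trait are dropped with reason \code{"missing"}. Rows of the
#' result are sorted by snp_id, making downstream estimates invariant to
#' the input record order.
#'
#' @param exposures a \linkS4class{GwasSummaryStats} or list of them
#'   (K exposures, first is the reference coding).
#' @param outcome a \linkS4class{GwasSummaryStats}.
#' @param palindromeWindow half-width of the ambiguous frequency band
#'   around 0.5 (default 0.08).
#' @return a \linkS4class{HarmonizedMRData}.
#' @export
harmonizeTraits <- function(exposures, outcome, palindromeWindow = 0.08) {
  if (is(exposures, "GwasSummaryStats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1L, is(outcome, "GwasSummaryStats"))
  for (e in exposures) stopifnot(is(e, "GwasSummaryStats"))

  allIds <- unique(unlist(c(lapply(exposures, snpIds), list(snpIds(outcome)))))
  shared <- Reduce(intersect, c(lapply(exposures, snpIds),
                                list(snpIds(outcome))))
  shared <- sort(shared)
  notShared <- sort(setdiff(allIds, shared))
  dropped <- data.frame(snp_id = notShared,
                        reason = rep("missing", length(notShared)),
                        stringsAsFactors = FALSE)
  if (!length(shared)) stop("no harmonizable instruments")

  ref <- exposures[[1]]@data
  ref <- ref[match(shared, ref$snp_id), , drop = FALSE]
  K <- length(exposures)
  L <- length(shared)
  betaX <- seX <- matrix(NA_real_, L, K,
                         dimnames = list(shared,
                                         vapply(exposures, traitName, "")))
  nX <- numeric(K)
  betaX[, 1] <- ref$beta; seX[, 1] <- ref$se; nX[1] <- stats::median(ref$n)
  flipped <- rep(FALSE, L)
  palinf <- rep(FALSE, L)
  reason <- rep(NA_character_, L)

  traits <- c(exposures[-1], list(outcome))
  aligned <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    td <- traits[[i]]@data
    td <- td[match(shared, td$snp_id), , drop = FALSE]
    a <- alignToReference(td, ref$effect_allele, ref$other_allele,
                          ref$eaf, palindromeWindow)
    reason <- ifelse(is.na(reason), a$reason, reason)
    flipped <- flipped | a$flipped
    palinf <- palinf | a$palindromic
    aligned[[i]] <- a
  }
  for (k in seq_len(K - 1)) {
    betaX[, k + 1] <- aligned[[k]]$beta
    seX[, k + 1] <- aligned[[k]]$se
    nX[k + 1] <- stats::median(aligned[[k]]$n)
  }
  out <- aligned[[length(aligned)]]

  keep <- is.na(reason)
  if (!any(keep)) stop("no harmonizable instruments")
  if (any(!keep))
    dropped <- rbind(dropped,
                     data.frame(snp_id = shared[!keep],
                                reason = reason[!keep],
                                stringsAsFactors = FALSE))
  dropped <- dropped[order(dropped$snp_id), , drop = FALSE]
  rownames(dropped) <- NULL

  new("HarmonizedMRData",
      snpIds = shared[keep],
      betaX = betaX[keep, , drop = FALSE],
      seX = seX[keep, , drop = FALSE],
      betaY = out$beta[keep], seY = out$se[keep],
      eaf = ref$eaf[keep],
      nX = nX, nY = stats::median(out$n[keep]),
      outcomeType = outcome@traitType,
      flags = data.frame(snp_id = shared[keep], flipped = flipped[keep],
                         palindromic_inferred = palinf[keep],
                         stringsAsFactors = FALSE),
      dropped = dropped)
}

#' Construct a HarmonizedMRData object directly
#'
#' Low-level constructor for already-aligned effect estimates, used by the
#' simulator and in tests. Rows are re-sorted by snp_id.
#'
#' @param snpIds variant ids.
#' @param betaX,seX exposure effect/SE matrix (vectors accepted for K = 1).
#' @param betaY,seY outcome effects and SEs.
#' @param eaf effect-allele frequencies (default 0.5).
#' @param nX,nY sample sizes.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @return a \linkS4class{HarmonizedMRData}.
#' @export
HarmonizedMRData <- function(snpIds, betaX, seX, betaY, seY,
                             eaf = NULL, nX = NA_real_, nY = NA_real_,
                             outcomeType = "continuous") {
  betaX <- as.matrix(betaX); seX <- as.matrix(seX)
  if (is.null(colnames(betaX)))
    colnames(betaX) <- colnames(seX) <- paste0("exposure", seq_len(ncol(betaX)))
  if (is.null(eaf)) eaf <- rep(0.5, length(snpIds))
  ord <- order(snpIds)
  empty <- data.frame(snp_id = character(), reason = character())
  new("HarmonizedMRData", snpIds = as.character(snpIds)[ord],
      betaX = betaX[ord, , drop = FALSE], seX = seX[ord, , drop = FALSE],
      betaY = betaY[ord], seY = seY[ord], eaf = eaf[ord],
      nX = rep_len(nX, ncol(betaX)), nY = nY, outcomeType = outcomeType,
      flags = data.frame(snp_id = as.character(snpIds)[ord], flipped = FALSE,
                         palindromic_inferred = FALSE,
                         stringsAsFactors = FALSE),
      dropped = empty)
}

#' Subset harmonized data to a set of SNPs
#'
#' @param data a \linkS4class{HarmonizedMRData}.
#' @param ids variant ids to keep.
#' @return a \linkS4class{HarmonizedMRData}.
#' @export
subsetSnps <- function(data, ids) {
  keep <- data@snpIds %in% ids
  if (!any(keep)) stop("no SNPs left after subsetting")
  new("HarmonizedMRData", snpIds = data@snpIds[keep],
      betaX = data@betaX[keep, , drop = FALSE],
      seX = data@seX[keep, , drop = FALSE],
      betaY = data@betaY[keep], seY = data@seY[keep], eaf = data@eaf[keep],
      nX = data@nX, nY = data@nY, outcomeType = data@outcomeType,
      flags = data@flags[keep, , drop = FALSE], dropped = data@dropped)
}
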