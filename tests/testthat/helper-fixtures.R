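# Fixture builders used across test files. Everything is generated in
# code under fixed seeds; no data files.

# a small well-formed association table
makeAssocTable <- function(n = 5, seed = 1, eaf = NULL, alleles = NULL) {
  set.seed(seed)
  if (is.null(alleles)) alleles <- cbind(rep("A", n), rep("G", n))
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.03)
  data.frame(snp_id = sprintf("rs%03d", seq_len(n)),
             chrom = rep("1", n), pos = as.integer(seq_len(n) * 2e7),
             effect_allele = alleles[, 1], other_allele = alleles[, 2],
             eaf = if (is.null(eaf)) runif(n, 0.1, 0.45) else eaf,
             beta = beta, se = se,
             pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = 1e5,
             stringsAsFactors = FALSE)
}

makeStats <- function(data, name = "trait", type = "continuous") {
  GwasSummaryStats(name, type, data)
}

# deterministic harmonized single-exposure dataset with a true slope
makeHarmonized <- function(L = 20, slope = 0.4, seed = 42, noise = 0,
                           sy = 0.02, sx = 0.005) {
  set.seed(seed)
  bx <- rnorm(L, 0, 0.1)
  bx[abs(bx) < 0.02] <- 0.02          # keep instruments away from zero
  by <- slope * bx + rnorm(L, 0, noise)
  HarmonizedMRData(sprintf("rs%03d", seq_len(L)), bx, rep(sx, L), by,
                   rep(sy, L), nX = 1e5, nY = 1e5)
}

# recode the allele representation of chosen records of a
# GwasSummaryStats: swap alleles, negate beta, complement eaf. This is
# the same association stated the other way around.
recodeAlleles <- function(stats, idx) {
  d <- associations(stats)
  ea <- d$effect_allele[idx]
  d$effect_allele[idx] <- d$other_allele[idx]
  d$other_allele[idx] <- ea
  d$beta[idx] <- -d$beta[idx]
  d$eaf[idx] <- 1 - d$eaf[idx]
  GwasSummaryStats(traitName(stats), traitType(stats), d)
}

# accuracy of a cluster assignment against planted mechanism labels,
# maximized over the label permutation (fitted cluster names are
# arbitrary)
clusterAccuracy <- function(assignments, truthLabels) {
  truth <- truthLabels[assignments$snp_id]
  mech <- setdiff(unique(truth), "null")
  fitLabs <- setdiff(unique(assignments$label), c("null", "junk", "unassigned"))
  best <- 0
  perms <- if (length(fitLabs) == 0) list(character(0)) else
    asplit(rbind(fitLabs, if (length(fitLabs) > 1) rev(fitLabs)), 1)
  for (p in perms) {
    map <- stats::setNames(p, mech[seq_along(p)])
    ok <- sum(assignments$label == map[truth], na.rm = TRUE)
    best <- max(best, ok)
  }
  best / sum(truth %in% mech)
}
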