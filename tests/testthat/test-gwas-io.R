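# Reading, validation, harmonization and instrument selection.

test_that("reading a delimited file validates records and maps columns", {
  d <- makeAssocTable(3)
  names(d)[names(d) == "eaf"] <- "FREQ"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

  s <- readSummaryStats(path, columnMap = c(eaf = "FREQ"),
                        traitType = "continuous", traitName = "t")
  expect_s4_class(s, "GwasSummaryStats")
  expect_equal(nrow(associations(s)), 3)
  expect_equal(associations(s)$beta, d$beta)

  # missing mapped column is a hard error naming the column
  expect_error(readSummaryStats(path, columnMap = c(eaf = "nope")), "eaf")
  # missing mandatory column named in the error
  d2 <- d; d2$FREQ <- NULL
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path2), "eaf")
  # empty file is a hard error
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(d), collapse = "\t"), path3)
  expect_error(readSummaryStats(path3), "empty")
})

test_that("invalid rows are dropped with logged reasons, counts conserve", {
  d <- makeAssocTable(6)
  d$se[2] <- 0
  d$eaf[3] <- 1.2
  d$effect_allele[4] <- "AT"
  d$snp_id[5] <- d$snp_id[1]
  s <- makeStats(d)
  expect_equal(nrow(associations(s)), 2)
  log <- droppedRecords(s)
  expect_setequal(log$reason, c("nonpositive_se", "eaf_out_of_range",
                                "non_snv_allele", "duplicate_snp_id"))
  expect_equal(nrow(associations(s)) + nrow(log), nrow(d))
})

test_that("inconsistent p-values warn but do not drop", {
  d <- makeAssocTable(3)
  d$pval <- zp <- 2 * pnorm(-abs(d$beta / d$se))
  d$pval[1] <- min(1, zp[1] * 100)
  expect_warning(makeStats(d), "inconsistent")
})

test_that("allele swaps are harmonized by negating beta and flipping eaf", {
  ex <- makeAssocTable(1, seed = 3)
  ex$effect_allele <- "A"; ex$other_allele <- "G"; ex$beta <- 0.1
  out <- ex
  out$effect_allele <- "G"; out$other_allele <- "A"
  out$beta <- 0.05; out$eaf <- 0.3
  h <- suppressWarnings(harmonizeTraits(makeStats(ex, "x"), makeStats(out, "y")))
  expect_equal(betaOutcome(h), -0.05)
  expect_true(h@flags$flipped)

  # identical coding passes through untouched
  h2 <- suppressWarnings(harmonizeTraits(makeStats(ex, "x"), makeStats(ex, "y")))
  expect_equal(betaOutcome(h2), ex$beta)
  expect_false(any(h2@flags$flipped))
})

test_that("palindromic SNPs follow the frequency-concordance rule", {
  al <- cbind(c("A", "C"), c("T", "G"))
  ex <- makeAssocTable(2, seed = 4, eaf = c(0.30, 0.50), alleles = al)
  out <- makeAssocTable(2, seed = 5, eaf = c(0.31, 0.50), alleles = al)
  h <- harmonizeTraits(makeStats(ex, "x"), makeStats(out, "y"),
                       palindromeWindow = 0.08)
  # concordant off-centre frequencies retained and flagged; eaf 0.5 dropped
  expect_equal(snpIds(h), "rs001")
  expect_true(h@flags$palindromic_inferred)
  expect_true("palindromic_ambiguous" %in% droppedRecords(h)$reason)

  # discordant sides are ambiguous too
  out2 <- makeAssocTable(1, seed = 6, eaf = 0.70,
                         alleles = cbind("A", "T"))
  ex2 <- makeAssocTable(1, seed = 7, eaf = 0.30, alleles = cbind("A", "T"))
  expect_error(harmonizeTraits(makeStats(ex2, "x"), makeStats(out2, "y")),
               "no harmonizable")
})

test_that("harmonization is involutive under outcome allele recoding", {
  sim <- generateDataset(simulationConfig(seed = 9, nSnps = 40))
  h1 <- harmonizeTraits(sim$exposure, sim$outcome)
  out2 <- recodeAlleles(sim$outcome, seq_len(40))
  h2 <- harmonizeTraits(sim$exposure, out2)
  expect_identical(snpIds(h1), snpIds(h2))
  expect_equal(betaOutcome(h2), betaOutcome(h1), tolerance = 1e-15)
  expect_equal(seOutcome(h2), seOutcome(h1), tolerance = 1e-15)
})

test_that("row counts conserve across harmonization drop reasons", {
  sim <- generateDataset(simulationConfig(seed = 10, nSnps = 30))
  ex <- sim$exposure
  out <- sim$outcome
  # remove some outcome SNPs so they drop as "missing"
  d <- associations(out)[-(1:5), ]
  h <- harmonizeTraits(ex, GwasSummaryStats("outcome", "continuous", d))
  expect_equal(length(snpIds(h)) + nrow(droppedRecords(h)), 30)
  expect_equal(sum(droppedRecords(h)$reason == "missing"), 5)
})

test_that("instrument selection applies the threshold and greedy pruning", {
  d <- makeAssocTable(5, seed = 8)
  d$pval <- c(1e-9, 1e-7, 1e-10, 0.5, 4e-8)
  d$chrom <- NA_character_; d$pos <- NA_integer_
  s <- suppressWarnings(makeStats(d))
  expect_warning(sel <- selectInstruments(s, 5e-8), "pruning skipped")
  expect_setequal(associations(sel)$pval, c(1e-9, 1e-10, 4e-8))

  # two SNPs 5 kb apart inside a 10 Mb window: smaller p wins
  d2 <- makeAssocTable(2, seed = 9)
  d2$chrom <- "2"; d2$pos <- c(1000000L, 1005000L)
  d2$pval <- c(1e-9, 1e-12)
  sel2 <- selectInstruments(suppressWarnings(makeStats(d2)), 5e-8,
                            pruneWindow = 1e7)
  expect_equal(associations(sel2)$pval, 1e-12)

  # nothing passes: hard error
  d3 <- makeAssocTable(3, seed = 10)
  d3$pval <- rep(0.5, 3)
  expect_error(selectInstruments(suppressWarnings(makeStats(d3))),
               "no instruments")
})

test_that("writeResults emits a fixed-schema TSV plus a JSON sidecar", {
  h <- makeHarmonized(20, noise = 0.01)
  est <- mrIVW(h)
  path <- file.path(withr::local_tempdir(), "ivw.tsv")
  writeResults(est, path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("method", "beta", "se", "ci_low", "ci_high",
                                 "pval", "n_snps", "Q", "Q_pval"))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$beta, est@beta, tolerance = 1e-12)
  expect_true(!is.null(side$metadata$version))

  # empty report gives a header-only TSV
  empty <- data.frame(snp_id = character(), ratio = numeric())
  path2 <- file.path(withr::local_tempdir(), "empty.tsv")
  writeResults(empty, path2)
  expect_equal(nrow(read.delim(path2)), 0)
})
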