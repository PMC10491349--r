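## Internal helpers: seeding, small numerics.

## Deterministic child-seed derivation from a master seed. Kept below
## 2^31 - 1 so the result is always a valid integer seed.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 1000003 * as.numeric(index)) %%
               2147483647)
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Two-sided normal p-value for an estimate and its SE.
zPval <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[se == 0 & beta == 0] <- 1
  pmax(p, .Machine$double.xmin)  # keep extreme associations representable
}

## Wald-normal 95% confidence limits.
waldCI <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(low = beta - z * se, high = beta + z * se)
}

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complementAllele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}
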