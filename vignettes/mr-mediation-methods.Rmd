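---
title: "Methods: two-sample MR mediation analysis in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation analysis in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

`mrmediate` estimates how much of an exposure's causal effect on an
outcome is transmitted through an intermediate trait, using only GWAS
summary statistics from non-overlapping samples. The structural model
behind everything is a linear causal diagram over a set of independent
genetic variants $j = 1, \dots, L$:

$$X \leftarrow \gamma_j G_j, \qquad
  M = \alpha X + \delta_j G_j, \qquad
  Y = \beta_{dir} X + \beta_{med} M + \theta_j G_j,$$

so that variant $j$'s true associations are $\gamma_j$ with the
exposure, $\alpha\gamma_j + \delta_j$ with the mediator, and
$(\beta_{dir} + \alpha\beta_{med})\gamma_j + \beta_{med}\delta_j +
\theta_j$ with the outcome. The estimands are the total effect
$\beta_{tot} = \beta_{dir} + \alpha\beta_{med}$, the indirect effect
$\alpha\beta_{med}$, and the proportion mediated
$\alpha\beta_{med}/\beta_{tot}$. $\theta_j \ne 0$ is horizontal
pleiotropy — the violation the robust estimators and outlier methods
exist to detect. For a binary outcome all $Y$-side coefficients live on
the log-odds scale; odds ratios appear only at reporting time, and the
product/difference decomposition on that scale carries the usual
non-collapsibility caveat (their equality is asserted only for
continuous outcomes).

Core MR assumptions: instruments are associated with the exposure
(checked via F statistics), share no confounder with the outcome, and
affect the outcome only through the exposure (probed by the Egger
intercept, Cochran's Q, outlier decomposition and Steiger filtering —
none of which can prove it).

# Estimators

**Wald ratio, IVW.** The per-variant estimate is
$\hat\beta_j = \hat\beta^Y_j / \hat\beta^X_j$ with first-order SE
$\sigma^Y_j/|\hat\beta^X_j|$ (a second-order form propagating the
exposure-side variance is available). IVW is the weighted regression of
outcome on exposure effects through the origin with weights
$1/(\sigma^Y_j)^2$. The default flavour is multiplicative random
effects: the fixed-effect SE is inflated by
$\max\{1, \sqrt{Q/(L-1)}\}$, which widens intervals under heterogeneity
without reweighting the points. Fixed effects are available by flag.

**MR-Egger.** Weighted regression *with* intercept after orienting all
exposure effects non-negative (the orientation is required for the
intercept to estimate average directional pleiotropy; it leaves the
slope unchanged). Both SEs scale by $\max\{1, \sqrt{Q/(L-2)}\}$.

**Weighted median.** The inverse-variance weighted median of the
ratios, obtained by linear interpolation of the cumulative weight
midpoints at 0.5; consistent while valid instruments hold over half the
total weight. Its SE comes from a seeded parametric bootstrap (default
1000 draws) resampling both sides from their reported SEs. Inputs are
first put in a canonical orientation so the bootstrap stream — and
hence the SE — is identical whatever allele coding the files used.

**MVMR.** Weighted regression of outcome effects on the $L \times K$
matrix of exposure effects without intercept; SEs scale by
$\max\{1,\sqrt{Q_A/(L-K)}\}$. Cross-exposure sampling covariance is set
to zero, which is exact for non-overlapping GWAS samples and a
documented limitation otherwise. Instruments are the union of the
per-exposure selections (variants missing in any trait are dropped).
Exact rank deficiency raises "collinear exposures". Conditional
instrument strength for exposure $k$ regresses its effect column on the
others with weights $1/(\sigma^{X_k}_j)^2$ and refers the weighted
residual sum of squares to $L-K+1$; values below 10 trigger a warning,
nothing more.

**Diagnostics.** Cochran's $Q = \sum_j w_j(\hat\beta_j -
\hat\beta)^2$ with $w_j = (\hat\beta^X_j)^2/(\sigma^Y_j)^2$;
$Q_A = \sum_j (\hat\beta^Y_j - x_j^\top\hat\beta)^2/(\sigma^Y_j)^2$.
Both use plug-in estimates rather than minimization — matching how the
statistics are reported alongside estimates; a minimized variant would
be an extension. Steiger filtering computes per-variant
$r^2 = t^2/(t^2 + n - 2)$ in each trait ($t = \hat\beta/\sigma$) and
removes variants explaining significantly more outcome than exposure
variance (z-test on the Fisher-transformed correlations). This $r^2$
form needs no trait-variance assumptions, at the price of being
approximate on the observed log-odds scale for binary outcomes.

# Outlier decomposition and clustering

**Radial.** The radial reparameterization regresses
$\hat\beta_j\sqrt{w_j}$ on $\sqrt{w_j}$ through the origin, making the
per-variant contribution $Q_j = w_j(\hat\beta_j - \hat\beta)^2$
explicit; with first-order weights the $Q_j$ sum to Cochran's Q exactly
(a tested identity). Modified second-order weights
$w_j = \big((\sigma^Y_j)^2/(\hat\beta^X_j)^2 +
\hat\beta^2(\sigma^X_j)^2/(\hat\beta^X_j)^2\big)^{-1}$ are iterated
with the estimate to a $10^{-8}$ fixed point (at most 100 iterations;
non-convergence is a hard error carrying the iteration trace). A
variant is flagged when the $\chi^2_1$ upper tail at $Q_j$ falls below
$0.05/L$ (Bonferroni is the only multiple-testing correction used);
ties at the maximal $Q_j$ flag all tied variants.

**PRESSO-style testing.** The global statistic is the sum of squared
standardized leave-one-out residuals, compared against `nSim`
(default 1000, minimum 100) parametric simulations under the fitted
model with each variant's reported SEs; the per-variant outlier test
compares each residual to its own simulated null with Bonferroni
correction; the distortion test compares the outlier-removed shift in
the IVW estimate against removals of random subsets of the same size.
When nothing is flagged the distortion test is skipped and the
corrected estimate equals the original. All three are seeded.

**Ratio clustering.** A mixture over the Wald ratios with *known*
per-variant variances: $K$ free normal components, a null component
with mean fixed at zero, and a junk component uniform over the observed
ratio range widened by ten times the largest ratio SE. EM updates the
means (precision-weighted) and mixing proportions; $K \in
\{0,\dots,K_{max}\}$ is selected by a BIC-style penalized
log-likelihood with $K$ mean parameters and $K+1$ free mixing
proportions. Numerical choices that matter: 20 seeded restarts per $K$,
with initial means drawn from the observed ratios jittered by the
*median* ratio SE (jitter at the scale of the largest SE lets restarts
land between basins, where a component's responsibilities collapse and
it dies); best fits containing an effectively empty substantive
component (summed responsibility < 0.5) are rejected for that $K$, as
they are degenerate restatements of a smaller model that would
otherwise occasionally win the selection by chasing single variants.
Variants are labelled only at conditional probability ≥ 0.9 (the
conservative reporting convention), else "unassigned"; numerical
identity with any particular clustering package is explicitly not a
goal — the contract is behavioural (recover planted mechanisms, isolate
nulls).

# Mediation

The *product* method multiplies the exposure-on-mediator effect (step
one, univariable IVW) by the mediator's MVMR direct effect on the
outcome; its SE is the Sobel form
$\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$ (the second-order term
$\sigma_a^2\sigma_b^2$ is available by flag but off by default, per the
Sobel convention). The *difference* method subtracts the MVMR direct
exposure effect from the total effect with propagated errors
$\sqrt{\sigma_{tot}^2 + \sigma_{dir}^2}$; the covariance between the
two (they share instruments) is ignored, an anti-conservative risk that
is documented rather than guessed at. The proportion mediated uses the
delta method for a ratio, with covariance zero by default; a Fieller
interval would be the natural alternative but is not the default. The
proportion may fall outside [0, 1] and is then reported as computed,
with a warning; a warning is also raised when the total effect is
within ten SEs of zero, where the ratio is unstable.

# The simulator

`generateDataset()` draws summary statistics directly from the
asymptotic sampling model rather than simulating genotypes: observed
effects are the truth plus independent normal noise with analytic SEs
$1/\sqrt{2p_j(1-p_j)n}$ for standardized continuous traits, with an
additional $\varphi(1-\varphi)$ case-fraction factor under the root on
the log-odds scale. This is exact for the quantities the estimators
consume, fast enough for desk-scale Monte Carlo, and gives every test a
closed-form truth. What it deliberately does *not* emulate: linkage
disequilibrium (variants sit ≥ 50 Mb apart, matching the post-clumping
regime the estimators assume), sample overlap, allele-frequency
estimation error, liability-scale binary genetics, and winner's-curse
interplay with external discovery. Passing tests therefore validate the
estimators under their own asymptotic model, not robustness to LD or
overlap. Allele codings are randomly swapped between traits so
harmonization is genuinely exercised; one master seed derives
deterministic per-trait child seeds, and identical configurations are
byte-identical.

The spec of the mediator arm deserves a note: with mediator effects
$\alpha\gamma_j$ alone, exposure and mediator columns would be
collinear and MVMR unidentifiable. The direct SNP-on-mediator effects
$\delta_j$ (field `deltaSD`) are therefore first-class: they are the
mediator's own instruments, exactly the role mediator GWAS hits play in
a real two-step analysis.

## Scenario presets and their parameters

The anchor preset `dense_area_default` encodes the
childhood-adiposity → dense-area → breast-cancer structure: binary
outcome, true total effect −0.41 (log-odds) with proportion mediated
0.56 ($\alpha = -0.56$, $\beta_{med} = 0.41$, $\beta_{dir} =
-0.1804$), 100 SNPs, samples of 50,000 per trait, MAF ~ U(0.1, 0.4),
$\gamma_j, \delta_j \sim N(0, 0.06^2)$. The effect-size SD is chosen so
that selected instruments have mean F in the tens-to-low-hundreds —
the strength regime of large-biobank adiposity instruments — keeping
weak-instrument dilution well below the recovery tolerance.
`null_mediation` sets $\alpha = 0$ with $\beta_{dir} = -0.41$
(non-null total, null indirect — the regime where the Sobel z is
asymptotically standard normal); `continuous_mediation` moves the
anchor effects to a continuous outcome, where product and difference
must agree.

`outlier_default` plants 3 of 21 instruments with outcome-effect shifts
of exactly five outcome-SEs (fixed MAF 0.25 so the shift is exact in
ratio-SE units). `clustered_dense_area` plants two mechanisms (slopes
+0.4 and −0.3, ten SNPs each) plus five null SNPs with
$\gamma_j \sim N(0.365, 0.02^2)$ at MAF 0.25, making every ratio SE
≈ 0.02 — uniform instrument strength, so assignment confidence reflects
mechanism separation rather than per-variant power.
`invalid_40pct` gives 40% of instruments directional pleiotropy (mean
0.06) with half-normal $\gamma$ (trait-increasing coding, without which
symmetric $\gamma$ would cancel the directional bias in IVW) and an
outcome sample of 200,000 — outcome GWAS are typically several-fold
larger than exposure GWAS in this design, and the larger sample is what
puts the weighted median inside its consistency regime while IVW
remains visibly biased. `directional_pleiotropy` gives every instrument
pleiotropy of mean 0.02 with InSIDE satisfied, the estimand of the
Egger intercept.

Calibration checks of Q and $Q_A$ use exposure/mediator samples of
500,000 against an outcome of 50,000: first-order weights ignore
exposure-side noise (the NOME approximation), and the $\chi^2$
reference for Q holds only in that regime — with equal sample sizes
mean Q is inflated by a factor $1 + \beta^2
(\sigma^X)^2/(\sigma^Y)^2$ by construction, which is a property of the
statistic, not a defect of the code.

All other defaults (palindromic frequency window 0.08, pruning window
10 Mb, p-threshold 5×10⁻⁸, bootstrap 1000, PRESSO simulations 1000,
assignment threshold 0.9, radial tolerance 10⁻⁸) are stated in the
function documentation; thresholds anchored to standard practice are
used as-is and none is tuned per dataset.

# Harmonization and degenerate inputs

All traits are aligned to the first exposure's allele coding: swapped
(or strand-complement swapped) codings negate the beta and complement
the frequency. Palindromic variants are kept only when both traits'
aligned frequencies fall outside [0.42, 0.58] on the same side of 0.5,
else dropped as ambiguous — a deterministic, documented stand-in for
toolchain conventions that are not fully specified anywhere; the rule
is involutive (re-flipping a file reproduces the same harmonized
dataset exactly, a tested property). Only A/C/G/T single-nucleotide
alleles are accepted; indels and mismatches drop with logged reasons,
and retained + dropped always equals the shared input count.
Harmonized rows are sorted by variant id, which — together with
canonical orientation inside the stochastic estimators — makes every
estimate invariant to file row order and allele coding, to machine
precision.

Degenerate inputs have defined behaviour rather than accidents: a
single instrument reduces IVW to its Wald ratio (no MRE inflation is
possible); Egger and the weighted median refuse fewer than three
instruments, PRESSO fewer than four; zero exposure effects are excluded
from ratios with a logged reason and all-zero exposure effects are a
hard error; a zero total effect makes the proportion mediated a hard
error rather than an Inf.

# Pipeline reproducibility

`runPipeline()` executes a validated plan (YAML or constructed in
code); validation returns the complete list of violations, not the
first. One global seed yields deterministic per-step child seeds, so a
plan rerun with the same seed reproduces every TSV, JSON sidecar and
report byte for byte; machine-specific paths are kept out of the
report for that reason. Monte-Carlo problem sizes used by the test
suite and the acceptance script (200 replicates for recovery and
concordance, 1000 for null calibration of the indirect effect, 500 for
Q calibration, 100 seeds for outlier detection, 20 for cluster
recovery) were chosen to keep Monte-Carlo error a small fraction of
each tolerance while the whole suite runs in minutes on one CPU.

# Known limitations

Positional pruning is a stand-in for LD clumping against a reference
panel, and proxy-variant substitution is out of scope: variants missing
from the outcome are dropped. The difference-method SE ignores the
total/direct covariance. Binary-outcome mediation is non-collapsible on
the log-odds scale, and Steiger $r^2$ is approximate there. The
clustering contract is behavioural, not numerically identical to any
external implementation. Estimates from real data inherit every caveat
of the source GWAS — population structure, overlap, selection — that
the simulator does not model.
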