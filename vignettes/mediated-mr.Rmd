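---
title: "Two-sample Mendelian randomization with two-step mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with two-step mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone, using genetic
variants (SNPs) as instrumental variables. Each instrument j contributes a
Wald ratio r_j = beta_out_j / beta_exp_j, an estimate of the causal effect
valid under the instrumental-variable assumptions (the SNP associates with
the exposure, shares no confounder with the outcome, and affects the
outcome only through the exposure). Because exposure and outcome effects
come from different cohorts, no individual-level data are needed.

The two-step (mediated) design decomposes the total effect c of an
exposure on an outcome into an indirect path through a mediator and a
direct remainder:

* stage 1: MR of exposure on mediator gives `a`;
* stage 2: MR of mediator on outcome gives `b`;
* total: MR of exposure on outcome gives `c`;
* indirect effect = `a * b`, direct effect `c' = c - a * b`, proportion
  mediated = `a * b / c`.

For a binary outcome the effects are on the log-odds scale and
`exp(beta)` is an odds ratio.

## Instrument selection

Instruments are selected per exposure by three filters, in order:

* association p-value strictly below `p_instrument` (default `1e-5`, the
  customary threshold for traits with few genome-wide-significant hits
  such as microbial taxa or immune-cell phenotypes);
* greedy LD clumping with window `clump_kb` = 10,000 kb and r²
  threshold 0.001: the most significant unclaimed SNP becomes an index,
  and unclaimed SNPs are discarded only when they are *both* within the
  window *and* in LD above the threshold with it (far-apart SNPs are kept
  regardless of r²; ties on p broken by chromosome and position so the
  result does not depend on input order);
* per-SNP F statistic strictly above `f_min` = 10. The default F is the
  Wald form `(beta/se)^2`, which needs no allele frequency or sample
  size; the frequency-based form `F = (n-2) r² / (1-r²)` with
  `r² = 2 f (1-f) beta²` is available where `eaf` and `n` are present.

Both thresholds are strict inequalities; boundary values are excluded.
SNPs absent from the LD reference are treated as independent and kept,
with a warning, since partial LD references are the norm.

## Harmonization

Summary panels are aligned onto the exposure's effect allele. When the
outcome panel reports the same pair of alleles in swapped order, its beta
is negated and allele frequency complemented. Palindromic SNPs (A/T,
C/G) carry no strand information in summary data; the default policy
drops them. The alternative, `infer_by_eaf`, keeps a palindromic SNP only
when both panels report allele frequencies on the same side of 0.5 and
outside an ambiguity band (default 0.08) around it. Allele comparison is
case-insensitive; indels pass through as literal strings. These rules are
a declared convention of this package: harmonization conventions differ
between published tools and summary files rarely state strand.

## Estimators

Five estimators run on each harmonized set, all returning beta, se,
two-sided p, OR = exp(beta) and a 95% CI exp(beta ± 1.959964 se):

* **IVW** — weighted least squares of outcome on exposure betas through
  the origin, weights 1/se_out². The default error model is
  multiplicative random effects: the fixed-effect se is inflated by
  sqrt(max(Q/(J-1), 1)), which guards against overdispersion but never
  deflates below the fixed-effect se. IVW is the primary estimator; a
  single SNP degrades to the Wald ratio.
* **MR-Egger** — the same regression with an intercept, after orienting
  every SNP so its exposure beta is nonnegative (Egger regression is not
  invariant to allele recoding; this orientation is the conventional
  resolution). The slope is the causal estimate; the intercept estimates
  the mean directional pleiotropic effect. The slope se carries the same
  multiplicative random-effects floor; the intercept se is left unscaled
  so that the intercept test is the exact weighted-regression t-test with
  J−2 degrees of freedom and keeps nominal size under no pleiotropy (a
  floored intercept se would make the test conservative and its p
  non-uniform under the null).
* **Weighted median** — the weighted median of the Wald ratios via
  cumulative standardized weights p_j = (S_j − w_j/2)/S_J interpolated at
  0.5; consistent while valid instruments hold more than half the
  weight.
* **Simple and weighted mode** — the argmax of a normal-kernel density
  over the ratios, bandwidth `phi · 0.9 · min(sd, mad) · J^(−1/5)` (mad
  on the normal-consistent scale), unit or inverse-variance weights;
  consistent when the largest cluster of ratios is the valid one.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1,000 replicates) perturbing both exposure and outcome betas by
their standard errors. All p-values are two-sided normal except the
Egger slope and intercept, which use the t distribution with J−2 df —
honest for the small instrument counts where Egger is typically run.

## Diagnostics

* **Cochran's Q** over the Wald ratios with first-order weights; Q is
  unitless and permutation-invariant.
* **Egger intercept test**, re-exposing the regression intercept above.
* **MR-PRESSO** global and per-SNP outlier tests with the
  residual-sum-of-squares statistic against leave-one-out IVW
  predictions; the global p uses the plus-one Monte-Carlo estimator
  (minimum reportable p = 1/(n_sim+1)), per-SNP ps are
  Bonferroni-adjusted. The distortion test is deliberately not
  implemented: the package reports detection, not bias correction.
* **Leave-one-out** IVW with a sign-flip flag per excluded SNP.

## Screening pipeline

`forward_screen()` runs instrument selection, harmonization and IVW for
each candidate exposure and passes traits with p strictly below
`alpha_screen` (default 0.05, uncorrected; Bonferroni and
Benjamini-Hochberg adjustments are available and applied before the pass
decision). `reverse_check()` swaps the roles and passes on
non-significance: reverse p **at or above** `alpha_reverse` passes, so a
boundary p of exactly 0.05 passes — non-significance is the desired
outcome there, and the boundary convention is documented rather than
silent. Per-trait failures (no instruments, no shared SNPs) are recorded
in the result table and never abort a batch.

`run_mediation_chain()` executes the three MRs with the full estimator
panel and diagnostics and assembles the mediation decomposition from the
IVW triple. Stage 2 instruments the mediator with its own variants:
SNPs that already instrument the exposure are excluded from the stage-2
instrument set. This matters: a SNP whose mediator association arises
through the exposure has mediator-outcome Wald ratio equal to the total
effect divided by `a`, not `b`, so leaving such SNPs in biases stage 2
toward c/a. Excluding them mirrors practice in two-sample two-step
studies where each trait contributes its own discovery GWAS.

Determinism is a contract: one master seed fans out to every stochastic
component (bootstraps, PRESSO, Monte-Carlo CIs) through a fixed string
hash (`derive_seed()`), so adding a component never shifts another's
stream, and identical inputs plus config give byte-identical reports.

## The synthetic generator

`generate_chain()` emulates the statistical structure the pipeline
assumes, directly at the summary level: per-SNP effects on the exposure
`gamma_j ~ N(0, sigma_gamma²)` and on the mediator
`delta_j ~ N(0, sigma_delta²)` (the mediator's own instruments), true
marginals exposure = gamma, mediator = a·gamma + delta, outcome =
(c_direct + a·b)·gamma + b·delta + alpha, with estimated betas adding
independent per-panel noise of scale `1/sqrt(2 f (1−f) n)` and minor
allele frequencies Uniform(0.05, 0.5). The three panels draw noise
independently, matching non-overlapping GWAS cohorts; binary-outcome
effects are treated as log-odds with the same normal noise model.
Horizontal pleiotropy is injected on the outcome: balanced
(`N(0, magnitude²)`, heterogeneity without bias) or directional
(`magnitude` on the exposure-increasing allele — planting it in a fixed
allele coding instead would cancel against the symmetric gamma
distribution and be invisible to Egger regression, which orients on the
exposure-increasing allele).

Mediator-specific instruments are a deliberate design choice: with only
exposure-driven SNPs, the stage-2 estimand is `(c_direct + a·b)/a`
rather than `b`, and no estimator could recover the stage-2 effect. The
generator therefore gives the mediator its own discovery panel, as real
two-step designs do.

Defaults (`j_exposure = j_mediator = 50`, `n = 50,000`, `sigma_gamma =
sigma_delta = 0.15`, `a = 0.3`, `b = −0.25`, `c_direct = −0.05`) give
strong instruments (median F in the hundreds) and the qualitative
signature studied in the package's validation suite: stage-1 positive,
stage-2 and total negative, all significant.

What the generator does **not** emulate: realistic MAF and LD spectra
(LD is constant within rectangular blocks, zero between), sample overlap
between cohorts, case-control ascertainment, winner's-curse-inducing
selection at genome-wide scale, or trait architectures with many weak
polygenic effects. Passing recovery tests therefore shows the
estimators and pipeline are correct under the stated model, not that
real-data results are unbiased.

## Numerical choices and degenerate inputs

* CI multiplier fixed at z = 1.959964 (95%).
* Wald ratio se is first-order `se_out/|beta_exp|` (a second-order form
  propagating exposure noise is available); the delta-method se of the
  product `a·b` omits the `a_se²·b_se²` cross term — at low
  signal-to-noise this understates the sd by a few percent, and the
  Monte-Carlo CI method is offered for that regime.
* Monte-Carlo p-values use the plus-one estimator; analytic p-values are
  clamped away from exact 0.
* All ratios identical: Q = 0 with p = 1; the mode estimator returns the
  common ratio; the weighted median interpolates to it.
* Zero exposure beta makes a Wald ratio undefined and is an error for
  the ratio-based estimators; in practice instrument selection removes
  such SNPs before any estimator runs.
* Proportion mediated is reported without truncation to [0, 1] and the
  opposite-sign (inconsistent mediation) case is flagged, not hidden.
* The total-is-zero decomposition returns the direct effect and an `NA`
  proportion with a warning.

## Validation problem sizes

The shipped verification suite runs at desk scale, chosen to keep the
full suite in minutes while leaving Monte-Carlo error well inside the
asserted bands: calibration of Cochran's Q at 2,000 replicates (J = 10,
n = 50,000), IVW bias/coverage at 1,000 replicates (J = 30), Egger
intercept uniformity at 1,000 replicates, MR-PRESSO detection and
calibration at 200 replicates (J = 25, with 1,000 simulations each),
weighted-median robustness at 500 replicates with 40% invalid
instruments, and the qualitative mediation signature at 100 replicates
of the full pipeline (J = 50 + 50, n = 50,000).

## Known limitations

* No multivariable MR; stage-2 contamination is handled by instrument
  exclusion, not joint modelling.
* No correlated-instrument (generalized) IVW: clumping at r² 0.001 is
  assumed to have removed LD.
* No Steiger directionality filtering; directionality is addressed by
  the explicit reverse-MR check instead.
* MR-PRESSO stops at detection (no distortion correction).
* The reported OR confidence level is fixed at 95%.
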