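---
title: "Causal triangulation: two-sample MR, one-sample MR and inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal triangulation: two-sample MR, one-sample MR and inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkin)
```

This vignette explains the statistical models behind `mrkin`, the
assumptions they rest on, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where a choice was genuinely open.

## The scientific setting

Coffee consumption and heaviness of smoking are strongly associated
observationally, but observational regressions cannot separate
causation from confounding or reverse causation. `mrkin` supports the
triangulation strategy for such questions: (i) two-sample Mendelian
randomization using published summary statistics, (ii) replication with
one-sample MR in an individual-level cohort, and (iii) bench kinetics
for the proposed mechanism — here, inhibition of CYP2A6, the enzyme
responsible for roughly 80% of nicotine's inactivation to cotinine, by
coffee constituents such as caffeic acid, quercetin and p-coumaric
acid. A causal claim is convincing only when all three lines point the
same way.

## Two-sample Mendelian randomization

### Model and assumptions

A SNP is a valid instrument when it (1) associates with the exposure,
(2) shares no common cause with the outcome, and (3) affects the
outcome only through the exposure. Under these assumptions the per-SNP
Wald ratio `beta_y / beta_x` estimates the causal effect in outcome
units per exposure unit (here: cigarettes/day, or SD units of plasma
cotinine, per cup of coffee per day).

The delta-method standard error is first-order by default,
`se = |se_y / beta_x|`, treating the exposure coefficient as fixed.
This is the standard choice when the exposure GWAS is much better
powered than the outcome association for each variant, and it is the
convention under which the packaged fixture tables reproduce their
published combined estimates; the second-order form, which propagates
`se_x`, is available via `wald_ratio(..., order = "second")`.

Per-SNP ratios are combined by fixed-effects inverse-variance
weighting. Fixed (not random) effects is deliberate: the instrument
sets are small (2–8 SNPs) and pre-pruned for independence, and no
heterogeneity statistic is computed. Confidence intervals are
`estimate ± 1.96 se` and p-values are two-sided normal, with no
small-sample t-correction — consistent with the interval convention of
the analyses the package reproduces.

### The weighted median

The weighted-median estimator guards the headline result against
pleiotropy: it remains consistent when up to half of the total weight
comes from invalid instruments. Sorted ratios receive normalized
cumulative mid-weights `p_j = (sum_{i<=j} w_i - w_j/2) / sum(w)` and
the estimate interpolates `(p_j, ratio_j)` linearly at `p = 0.5`; below
`p_1` or above `p_m` the extreme ratio is returned. Its standard error
has no closed form, so it is bootstrapped parametrically: each
replicate redraws every ratio from `N(ratio_j, se_j)` and recomputes
the median. The default is 1000 replicates and the seed argument is
mandatory — bootstrap results are bit-reproducible and never
wall-clock-seeded.

### Harmonization and LD pruning

Exposure and outcome tables must refer each beta to the same allele.
Matching allele pairs are kept; swapped pairs flip the outcome beta's
sign; anything else is an error naming the SNP. Palindromic (A/T, C/G)
SNPs are rejected by default (`palindromic = "strict"`): without allele
frequencies, strand errors in such SNPs are silent sign errors, and
none of the eight packaged instrument SNPs is palindromic, so
frequency-based resolution is intentionally not implemented.

`ld_prune` enforces a pairwise r² ceiling (the packaged instrument sets
were pruned at r² < 0.0006). When a pair violates the ceiling, the
member to drop is chosen uniformly at random under an explicit seed;
pairs are scanned in sorted-rsID order so the random stream, and hence
the result, is reproducible.

## One-sample Mendelian randomization

On individual-level data, gene–exposure and gene–outcome associations
are estimated in the same sample: for each SNP, linear regressions of
exposure and outcome on allele dosage (0/1/2), optionally adjusted for
covariates, yield `beta_x` and `beta_y`; Wald ratios are then combined
exactly as in the two-sample case. A weighted genetic risk score
(dosages weighted by external exposure betas) serves as the instrument
whose strength is reported as the squared t-statistic of the score in
the exposure regression; F > 10 is the conventional weak-instrument
threshold. SNPs whose in-cohort exposure association is numerically
negligible (|beta_x| < 1e-8 by default) are excluded with a warning
rather than contributing an unstable ratio.

Observational and per-SNP regressions use heteroscedasticity-robust
HC3 sandwich standard errors by default (the variant with small-sample
leverage correction), since cigarettes/day residuals are far from
normal; set `robust = FALSE` for classical errors. The analysis-sample
convention — current smokers reporting non-zero exposure — is an
explicit filter (`filter_analysis_sample`), not an implicit side
effect.

## Power

For a continuous exposure and outcome, the instrument explains a
fraction R² of exposure variance and the standardized effect is
`b = beta * sd_x / sd_y`. The non-centrality parameter is
`NCP = n R² b²` and two-sided power at level alpha is
`pnorm(sqrt(NCP) - z) + pnorm(-sqrt(NCP) - z)`. The far-tail second
term matters only near the null, but including it makes the size exact
at `beta = 0` (power equals alpha), which the tests assert. With the
replication design values — n = 8072, exposure SD 2 cups/day, outcome
SD 8.5 cigarettes/day, beta = 1.5, alpha = 0.05 — this formula gives
61% power at R² = 0.005 and 89% at R² = 0.01.

## Enzyme-inhibition kinetics

### Rate law and plot geometry

All four reversible inhibition types are special cases of
`v = Vmax S / (Km (1 + I/Ki_c) + S (1 + I/Ki_u))` with `Ki_c` the
competitive-component and `Ki_u` the uncompetitive-component constant
(infinite = absent; equal = noncompetitive). Two classical
linearizations identify the type:

* **Dixon** (1/v vs I, one line per substrate level): lines intersect
  at `I = -Ki_c`, `y = (1 - Ki_c/Ki_u)/Vmax`; parallel lines signal a
  purely uncompetitive inhibitor.
* **Cornish–Bowden** (S/v vs I): lines intersect at `I = -Ki_u`,
  `y = Km (1 - Ki_u/Ki_c)/Vmax`; parallel lines signal a purely
  competitive inhibitor, and an intersection on the I-axis signals
  noncompetitive inhibition.

Both are fitted by unweighted ordinary least squares per substrate
level, mirroring graphical laboratory practice. With more than two
substrate levels the pairwise intersections are reduced by the median —
robust to one noisy line — and `Ki` is minus the median abscissa.

### Deciding "parallel" and "on the axis"

These two decisions carry the classification. Exact geometry is settled
by a relative slope-spread tolerance (< 0.02 declares parallel).
For noisy data a fixed relative tolerance is not usable — at 5%
velocity CV, estimated slopes of truly parallel lines routinely differ
by more than 2% — so parallelism is tested jointly: an ANCOVA F-test
compares a common-slope model against one slope per substrate level,
and lines are declared parallel unless the slopes differ at
`alpha_par = 0.01`. The Cornish–Bowden intersection counts as "on the
axis" when its |y| is below `y_rel_tol = 0.25` of the median
Cornish–Bowden intercept magnitude, a scale-free criterion calibrated
so that both the noncompetitive and the mixed round-trips stay above
90% accuracy at 5% CV in the package's simulations. When both plot
families are parallel (inconsistent geometry), the verdict is
`"undetermined"` with diagnostics rather than an error.

### Mechanism-based inhibition

A mechanism-based inhibitor is activated by the enzyme and inactivates
it irreversibly; it shows a larger activity loss when enzyme and
inhibitor are pre-incubated before substrate addition. The test
computes percent activity remaining (100·v(I)/v(0), replicate-averaged)
per arm and applies a one-sided paired t-test across inhibitor
concentrations at alpha = 0.05. A pre-incubated arm that is equal to or
*higher* than the control is never flagged.

### Physiological prediction

`fractional_inhibition` converts a plasma inhibitor concentration and a
Ki into the fraction of activity lost: `I/(I + Ki)` in the
low-substrate limit (nicotine concentrations in vivo are far below the
CYP2A6 Km), or the full competitive expression when substrate and Km
are supplied. `mg_per_l_to_uM` performs the plasma unit conversion;
note that 1.28 mg/l of caffeic acid (MW 180.16) computes to 7.10 μM,
not the 7.12 μM sometimes quoted — the package reports its own
arithmetic and flags the 0.02 μM discrepancy rather than forcing
agreement.

## The synthetic-data generators

### What they emulate

`generate_cohort` draws independent Hardy–Weinberg genotypes, a
standard-normal latent confounder U, and linear structural equations
`X = sum(gamma_j G_j) + c_x U + eps_x`,
`Y = beta X + c_y U + eps_y`. The defaults are the package's emulation
of a coffee-and-smoking analysis cohort and are fixed once: n = 8072
(the replication analysis-sample size), per-allele exposure effects
equal to the eight published betas (0.03–0.09 cups/day), causal effect
−1.5 cigarettes/day per cup/day (the magnitude of interest),
confounder paths 0.5 and 2, and residual SDs 1.94 and 8.08 chosen so
the marginal exposure and outcome SDs are approximately 2 and 8.5.
Effect-allele frequencies are not published for this instrument set, so
plausible European frequencies were fixed per SNP. The observational
slope in such a cohort is biased by exactly
`c_x c_y / Var(X)` relative to beta — a closed form the tests verify —
while MR remains consistent.

`generate_two_sample_summary` draws two *independent* cohorts and takes
exposure associations from one and outcome associations from the other,
reproducing the non-overlapping-samples structure of two-sample MR,
with an optional random allele-label swap to exercise harmonization.

`generate_kinetic_dataset` evaluates the rate law on a design grid and
multiplies by log-normal noise parameterized to have mean exactly 1 and
coefficient of variation `cv` (laboratory velocity error is
scale-proportional). Time-dependent inactivation is represented as a
Vmax multiplier applied to the inhibitor-containing wells of the
pre-incubated arm only — inhibitor-free reference wells are unaffected,
since inactivation requires the inhibitor.

### What they do not emulate

No linkage disequilibrium between instrument SNPs (the analyses assume
post-pruning independence; an LD matrix can still be attached to
exercise `ld_prune`), no genotyping error, missingness, selection
effects or population stratification, no integer-valued "cups per day"
reporting, and no systematic (non-multiplicative) assay error. Passing
the property suite therefore shows the estimators are correct under the
stated models, not that real data meet those models.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to make Monte-Carlo error
small relative to the tolerance being asserted: two-sample CI coverage
uses 100 replicates of 50 000 individuals per sample; parameter
recovery uses single cohorts of 100 000; classifier accuracy uses 200
replicates per inhibition model on a 4-substrate (0.5–4 × Km) × 4
inhibitor × 2 replicate design; Ki recovery uses 200 replicates of the
2 × 4 × 2 design with Ki = 152 μM, Vmax = 1 and Km = 50 μM (assay Km
and Vmax are not published; these are realistic round values and only
scale the plots). Degenerate inputs fail loudly: zero exposure betas,
zero-variance scores, non-positive SEs, mismatched pre-incubation
grids and insufficient substrate/inhibitor levels are all errors, not
silent exclusions — except the near-null per-SNP exposure filter in
one-sample MR, which warns and logs.

## Limitations

* Fixture-based reproduction is limited by table precision: published
  exposure betas carry two decimals, so combined estimates match to
  about ±0.1, not bit-exactly.
* The weighted median's bootstrap SE is approximate for very few SNPs
  (a warning fires below three).
* Dixon/Cornish–Bowden Ki estimation inherits the known statistical
  weaknesses of linearized fits; `classify_inhibition` reports line
  diagnostics so a nonlinear refit can be layered on when velocities
  at extreme concentrations are unreliable.
* The power formula is asymptotic-normal; it does not model weak
  instruments, whose bias the one-sample simulations make visible at
  small per-SNP F.
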