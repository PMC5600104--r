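# mrkin

Causal triangulation for exposure–outcome questions that can be attacked
from three directions at once: **two-sample Mendelian randomization**
(MR) on published GWAS summary statistics, **one-sample MR** on
individual-level cohort data, and **enzyme-inhibition kinetics** for the
candidate biological mechanism. The package grew out of the question of
whether coffee consumption causally changes heaviness of smoking
(cigarettes/day), with CYP2A6-mediated nicotine metabolism as the
candidate pathway, and ships the published per-SNP summary statistics
for that analysis as ready-to-run fixtures.

## What it computes

**Two-sample MR.** For each SNP *j* with exposure association
(β<sub>xj</sub>, se<sub>xj</sub>) and outcome association
(β<sub>yj</sub>, se<sub>yj</sub>), the Wald ratio and its first-order
delta-method standard error are

&nbsp;&nbsp;β̂<sub>j</sub> = β<sub>yj</sub>/β<sub>xj</sub>,&nbsp;&nbsp;
se<sub>j</sub> = |se<sub>yj</sub>/β<sub>xj</sub>|,

combined by fixed-effects inverse-variance weighting
(w<sub>j</sub> = se<sub>j</sub><sup>−2</sup>):

&nbsp;&nbsp;β̂ = Σ w<sub>j</sub> β̂<sub>j</sub> / Σ w<sub>j</sub>,&nbsp;&nbsp;
se = (Σ w<sub>j</sub>)<sup>−1/2</sup>,

with the pleiotropy-robust weighted-median estimator (cumulative
mid-weight interpolation at probability 0.5, parametric-bootstrap SE) as
a sensitivity analysis. Harmonization, LD pruning and the nested
8-/6-/2-SNP instrument models are handled by the `instruments`
functions.

**One-sample MR.** Weighted genetic risk scores, instrument-strength
F-statistics, observational regression with HC3 sandwich standard
errors, and in-cohort per-SNP Wald ratios combined by IVW.

**Power.** Analytic power for an MR design with continuous exposure and
outcome: NCP = n·R²·(β·σ<sub>x</sub>/σ<sub>y</sub>)², power =
Φ(√NCP − z<sub>1−α/2</sub>) + Φ(−√NCP − z<sub>1−α/2</sub>).

**Kinetics.** The mixed-inhibition rate law
v = V<sub>max</sub>S / (K<sub>m</sub>(1 + I/K<sub>ic</sub>) + S(1 + I/K<sub>iu</sub>)),
Dixon-plot K<sub>i</sub> estimation, Cornish–Bowden inhibition-type
classification, pre-incubation tests for mechanism-based inhibition and
fractional-inhibition prediction at plasma concentrations.

**Synthetic data.** Confounded structural-equation cohorts, two-sample
summary statistics and noisy velocity datasets, all with known ground
truth and explicit seeds, used throughout the test suite to validate
every estimator.

## Worked example

```r
library(mrkin)

set <- load_fixture_set("tag")       # coffee exposure vs cigarettes/day
res <- run_two_sample_mr(set, models = c("8-SNP", "6-SNP", "2-SNP"),
                         methods = "IVW-FE")
res[["8-SNP/IVW-FE"]]
#> IVW-FE causal estimate (8 SNPs)
#>   beta = -1.504, se = 0.692, 95% CI = -2.861 to -0.147, p = 0.0299

weighted <- run_two_sample_mr(set, models = "8-SNP",
                              methods = "weighted-median", seed = 1)
weighted[[1]]$estimate
#> [1] -2.152178

mr_power(n = 8072, r_squared = 0.005, beta = 1.5, sd_x = 2, sd_y = 8.5)
#> [1] 0.611139

100 * fractional_inhibition(inhibitor_uM = 6.16, ki_uM = 156)
#> [1] 3.798717
```

The eight-SNP IVW estimate says each additional cup of coffee per day
corresponds to about 1.5 fewer cigarettes per day in the two-sample
data, with a confidence interval excluding zero; the weighted median
agrees in direction. The power call shows the replication design had
61% power at instrument R² = 0.005, and the kinetics call shows a
plasma caffeic-acid concentration of 6.16 μM against a K<sub>i</sub> of
156 μM inhibits nicotine metabolism by under 4% — too little to explain
an effect of that size.

## Layout

- `R/` — instruments, MR estimators, one-sample MR, power, kinetics,
  synthetic-data generators, pipeline wrappers
- `inst/extdata/` — published per-SNP summary-statistics tables
- `vignettes/causal-triangulation.Rmd` — models, assumptions, design
  choices and limitations
- `tests/testthat/` — unit, property and end-to-end acceptance tests
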