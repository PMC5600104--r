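Package: mrkin
Title: Mendelian Randomization Estimators, Power Analysis and Enzyme
    Inhibition Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for causal triangulation combining two-sample
    Mendelian randomization from GWAS summary statistics (Wald ratios,
    fixed-effects inverse-variance-weighted meta-analysis, the
    pleiotropy-robust weighted-median estimator), one-sample Mendelian
    randomization on individual-level cohorts (weighted genetic risk
    scores, instrument-strength F-statistics, robust observational
    regression), analytic power calculation for instrumental-variable
    designs with continuous exposure and outcome, and cytochrome P450
    enzyme-inhibition kinetics (velocity laws for competitive,
    uncompetitive, non-competitive and mixed inhibition, Dixon-plot Ki
    estimation, Cornish-Bowden inhibition-type classification,
    pre-incubation tests for mechanism-based inhibition, and fractional
    inhibition prediction at physiological inhibitor concentrations).
    Synthetic-data generators with known ground truth support validation
    of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    metafor,
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
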