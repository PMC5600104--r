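#' Restrict a cohort to current smokers with non-zero exposure
#'
#' Applies the analysis-sample filter used throughout the one-sample
#' pipeline: individuals must report exposure greater than zero and,
#' when a `smoker` covariate is present, be flagged as current smokers.
#'
#' @param cohort a `cohort` object (see [generate_cohort()]).
#' @return The filtered `cohort`.
#' @export
filter_analysis_sample <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- cohort$exposure > 0
  if (!is.null(cohort$covariates$smoker))
    keep <- keep & cohort$covariates$smoker
  cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  cohort$exposure <- cohort$exposure[keep]
  cohort$outcome <- cohort$outcome[keep]
  cohort$covariates <- cohort$covariates[keep, , drop = FALSE]
  cohort
}

#' Weighted genetic risk score
#'
#' Per-individual weighted allele score
#' `score_i = sum_j weight_j * dosage_ij`, with weights typically the
#' per-allele exposure effects from an external GWAS.
#'
#' @param cohort a `cohort`.
#' @param weights named numeric vector with a weight for every SNP in
#'   the cohort's genotype matrix; defaults to the weights recorded in
#'   `cohort$snp_meta`.
#' @return Numeric vector of scores, one per individual.
#' @export
compute_grs <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  snps <- colnames(cohort$genotypes)
  if (is.null(weights)) {
    weights <- cohort$snp_meta$weight
    names(weights) <- cohort$snp_meta$snp_id
  }
  missing_w <- setdiff(snps, names(weights))
  if (length(missing_w))
    stop("no weight for SNP(s): ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  as.vector(cohort$genotypes %*% weights[snps])
}

build_covariate_matrix <- function(cohort, covariates) {
  if (!length(covariates)) return(NULL)
  missing_c <- setdiff(covariates, names(cohort$covariates))
  if (length(missing_c))
    stop("unknown covariate(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  as.matrix(cohort$covariates[covariates])
}

#' Instrument strength of a genetic risk score
#'
#' Regresses the exposure on the score (plus optional covariates) and
#' reports the instrument-strength F-statistic (the squared t-statistic
#' of the score term) and the incremental exposure variance explained
#' by the score. F > 10 is the conventional threshold above which weak
#' instrument bias is considered negligible.
#'
#' @param scores per-individual genetic risk score.
#' @param exposure per-individual exposure values.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return List with `f_statistic` and `r_squared`; a perfect
#'   (noise-free) instrument yields `r_squared = 1` and infinite F.
#' @export
instrument_strength <- function(scores, exposure, covariates = NULL) {
  if (stats::var(scores) == 0)
    stop("score has zero variance", call. = FALSE)
  n <- length(exposure)
  if (is.null(covariates)) {
    fit <- stats::lm(exposure ~ scores)
    fit0 <- stats::lm(exposure ~ 1)
  } else {
    fit <- stats::lm(exposure ~ scores + covariates)
    fit0 <- stats::lm(exposure ~ covariates)
  }
  if (n <= length(stats::coef(fit)) + 1L)
    stop("too few observations for the regression", call. = FALSE)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum(stats::residuals(fit0)^2)
  tss <- sum((exposure - mean(exposure))^2)
  r2 <- (rss0 - rss1) / tss
  if (rss1 <= 1e-12 * tss) {
    warning("perfect instrument: F unbounded")
    return(list(f_statistic = Inf, r_squared = r2))
  }
  tval <- summary(fit)$coefficients["scores", "t value"]
  list(f_statistic = tval^2, r_squared = r2)
}

robust_coef <- function(fit, term, robust = TRUE) {
  b <- stats::coef(fit)[[term]]
  if (robust) {
    V <- sandwich::vcovHC(fit, type = "HC3")
    se <- sqrt(V[term, term])
  } else {
    se <- summary(fit)$coefficients[term, "Std. Error"]
  }
  c(beta = b, se = se)
}

#' Observational exposure-outcome association
#'
#' Linear regression of the outcome on the exposure with optional
#' covariate adjustment. By default the standard error is
#' heteroscedasticity-robust (HC3 sandwich with small-sample leverage
#' correction), guarding against non-normal residuals. In a confounded
#' cohort this slope is biased away from the causal effect by
#' `confounder_to_x * confounder_to_y / Var(X)`.
#'
#' @param cohort a `cohort`.
#' @param covariates character vector of covariate column names to
#'   adjust for.
#' @param robust use sandwich (HC3) standard errors (default `TRUE`).
#' @return List with `beta`, `se`, `ci_low`, `ci_high`.
#' @export
observational_association <- function(cohort, covariates = character(),
                                      robust = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  C <- build_covariate_matrix(cohort, covariates)
  y <- cohort$outcome
  x <- cohort$exposure
  fit <- if (is.null(C)) stats::lm(y ~ x) else stats::lm(y ~ x + C)
  if (any(is.na(stats::coef(fit))))
    stop("degenerate design matrix in observational regression",
         call. = FALSE)
  perfect <- sum(stats::residuals(fit)^2) < 1e-12 * sum(y^2)
  cf <- if (perfect)
    c(beta = unname(stats::coef(fit)[["x"]]), se = 0)
  else robust_coef(fit, "x", robust)
  list(beta = unname(cf["beta"]), se = unname(cf["se"]),
       ci_low = unname(cf["beta"] - 1.96 * cf["se"]),
       ci_high = unname(cf["beta"] + 1.96 * cf["se"]))
}

#' One-sample Mendelian randomization on individual-level data
#'
#' For each SNP, the gene-exposure and gene-outcome associations are
#' estimated in-cohort by linear regression of exposure and outcome on
#' the allele dosage (covariate-adjusted as configured); the per-SNP
#' Wald ratios are then combined by fixed-effects inverse-variance
#' meta-analysis, with the weighted median available as a
#' pleiotropy-robust sensitivity analysis.
#'
#' SNPs whose in-cohort exposure association is smaller in magnitude
#' than `min_beta_x` are excluded with a warning (their Wald ratio is
#' unstable).
#'
#' @param cohort a `cohort`.
#' @param covariates covariate column names to adjust both regressions
#'   for.
#' @param robust use HC3 sandwich standard errors in the per-SNP
#'   regressions (default `TRUE`).
#' @param min_beta_x exclusion threshold for near-null exposure
#'   associations (default 1e-8).
#' @param method `"IVW-FE"` (default) or `"weighted-median"`.
#' @param n_boot,seed bootstrap settings for the weighted median.
#' @return An `mr_result` (see [ivw_fixed_effects()]).
#' @export
one_sample_mr <- function(cohort, covariates = character(),
                          robust = TRUE, min_beta_x = 1e-8,
                          method = c("IVW-FE", "weighted-median"),
                          n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort"))
  C <- build_covariate_matrix(cohort, covariates)
  snps <- colnames(cohort$genotypes)
  rows <- lapply(snps, function(s) {
    g <- cohort$genotypes[, s]
    fx <- if (is.null(C)) stats::lm(cohort$exposure ~ g) else
      stats::lm(cohort$exposure ~ g + C)
    fy <- if (is.null(C)) stats::lm(cohort$outcome ~ g) else
      stats::lm(cohort$outcome ~ g + C)
    cx <- robust_coef(fx, "g", robust)
    cy <- robust_coef(fy, "g", robust)
    data.frame(snp_id = s, beta_x = cx["beta"], se_x = cx["se"],
               beta_y = cy["beta"], se_y = cy["se"],
               stringsAsFactors = FALSE)
  })
  per_snp <- do.call(rbind, rows)
  rownames(per_snp) <- NULL
  weak <- abs(per_snp$beta_x) < min_beta_x
  if (any(weak)) {
    warning("excluding SNP(s) with near-null exposure association: ",
            paste(per_snp$snp_id[weak], collapse = ", "))
    per_snp <- per_snp[!weak, , drop = FALSE]
  }
  if (!nrow(per_snp))
    stop("no SNP with a usable exposure association", call. = FALSE)
  set <- instrument_set(per_snp, model_label = "custom")
  est <- wald_ratios(set, order = "first")
  if (method == "IVW-FE") ivw_fixed_effects(est)
  else weighted_median(est, n_boot = n_boot, seed = seed)
}
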