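#' Specification of a synthetic MR cohort
#'
#' Defines the structural model used to generate individual-level data
#' with known ground truth: independent Hardy-Weinberg genotypes, a
#' standard-normal latent confounder U, exposure
#' `X = sum_j gamma_j G_ij + confounder_to_x * U + N(0, sd_ex)` and
#' outcome
#' `Y = beta_causal * X + confounder_to_y * U + N(0, sd_ey)`.
#'
#' The defaults emulate a coffee-and-smoking analysis cohort: eight
#' biallelic SNPs with per-allele exposure effects of 0.03-0.09
#' cups/day, marginal exposure SD about 2 cups/day, marginal outcome SD
#' about 8.5 cigarettes/day at the default causal effect of -1.5
#' cigarettes/day per cup/day, and moderate positive confounding.
#'
#' @param n number of individuals.
#' @param mafs named vector of effect-allele frequencies in (0, 1).
#' @param gamma per-SNP effects on the exposure (same names as `mafs`).
#' @param beta_causal causal effect of exposure on outcome.
#' @param confounder_to_x,confounder_to_y confounding path coefficients.
#' @param sd_ex,sd_ey residual standard deviations of exposure and
#'   outcome.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 8072,
                        mafs = with(default_snp_meta(),
                                    stats::setNames(maf, snp_id)),
                        gamma = with(default_snp_meta(),
                                     stats::setNames(weight, snp_id)),
                        beta_causal = -1.5,
                        confounder_to_x = 0.5,
                        confounder_to_y = 2,
                        sd_ex = 1.94,
                        sd_ey = 8.08) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(mafs) != length(gamma))
    stop("mafs and gamma must have equal length", call. = FALSE)
  if (any(mafs <= 0 | mafs >= 1))
    stop("allele frequencies must be in (0, 1)", call. = FALSE)
  if (sd_ex < 0 || sd_ey < 0)
    stop("residual SDs must be >= 0", call. = FALSE)
  if (is.null(names(mafs)))
    names(mafs) <- paste0("snp", seq_along(mafs))
  names(gamma) <- names(mafs)
  structure(list(n = as.integer(n), mafs = mafs, gamma = gamma,
                 beta_causal = beta_causal,
                 confounder_to_x = confounder_to_x,
                 confounder_to_y = confounder_to_y,
                 sd_ex = sd_ex, sd_ey = sd_ey),
            class = "cohort_spec")
}

#' Default SNP metadata for the coffee-consumption instrument
#'
#' The eight coffee-consumption SNPs with their effect/other alleles,
#' per-allele exposure weights (cups/day) and plausible European
#' effect-allele frequencies used by the synthetic cohort generator.
#'
#' @return Data frame with columns `snp_id`, `gene`, `effect_allele`,
#'   `other_allele`, `weight`, `maf`.
#' @export
default_snp_meta <- function() {
  data.frame(
    snp_id = c("rs1260326", "rs1481012", "rs4410790", "rs7800944",
               "rs17685", "rs6265", "rs2470893", "rs9902453"),
    gene = c("GCKR", "ABCG2", "AHR", "MLXIPL", "POR", "BDNF",
             "CYP1A1", "EFCAB5"),
    effect_allele = c("C", "A", "C", "C", "A", "C", "T", "G"),
    other_allele = c("T", "G", "T", "T", "G", "T", "C", "A"),
    weight = c(0.03, 0.03, 0.05, 0.06, 0.05, 0.03, 0.09, 0.03),
    maf = c(0.39, 0.11, 0.63, 0.81, 0.28, 0.80, 0.28, 0.47),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic individual-level cohort
#'
#' Draws genotypes, confounder and noise according to a
#' [cohort_spec()]; the generating parameters are recorded in
#' `true_params` so estimators can be validated against ground truth.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; the same spec and seed always reproduce
#'   the identical cohort.
#' @return An object of class `"cohort"`: list with `genotypes`
#'   (n x n_snps dosage matrix, columns named by SNP), `exposure`,
#'   `outcome`, `covariates` (data frame with `age`, `sex`, `smoker`),
#'   `snp_meta` and `true_params`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- spec$n
  m <- length(spec$mafs)
  G <- matrix(stats::rbinom(n * m, 2L, rep(spec$mafs, each = n)),
              nrow = n, ncol = m,
              dimnames = list(NULL, names(spec$mafs)))
  U <- stats::rnorm(n)
  X <- as.vector(G %*% spec$gamma) + spec$confounder_to_x * U +
    stats::rnorm(n, sd = spec$sd_ex)
  Y <- spec$beta_causal * X + spec$confounder_to_y * U +
    stats::rnorm(n, sd = spec$sd_ey)
  meta <- default_snp_meta()
  snp_meta <- if (identical(names(spec$mafs), meta$snp_id)) meta else
    data.frame(snp_id = names(spec$mafs),
               gene = NA_character_,
               effect_allele = rep_len(c("A", "G"), m),
               other_allele = rep_len(c("G", "A"), m),
               weight = unname(spec$gamma), maf = unname(spec$mafs),
               stringsAsFactors = FALSE)
  covariates <- data.frame(
    age = round(stats::rnorm(n, 55, 8)),
    sex = stats::rbinom(n, 1L, 0.5),
    smoker = rep(TRUE, n)
  )
  structure(list(genotypes = G, exposure = X, outcome = Y,
                 covariates = covariates, snp_meta = snp_meta,
                 true_params = unclass(spec)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNP(s)\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  exposure SD %.2f, outcome SD %.2f, true beta %.3g\n",
              stats::sd(x$exposure), stats::sd(x$outcome),
              x$true_params$beta_causal))
  invisible(x)
}

# Vectorized simple regressions of a phenotype on each genotype column:
# slope, standard error per SNP (intercept included, no covariates).
simple_reg_by_snp <- function(phenotype, G) {
  n <- length(phenotype)
  gm <- colMeans(G)
  sxx <- colSums(G^2) - n * gm^2
  sxy <- as.vector(crossprod(G, phenotype)) - n * gm * mean(phenotype)
  beta <- sxy / sxx
  syy <- sum((phenotype - mean(phenotype))^2)
  rss <- syy - beta * sxy
  se <- sqrt(rss / ((n - 2) * sxx))
  data.frame(snp_id = colnames(G), beta = beta, se = se,
             stringsAsFactors = FALSE)
}

#' Generate two-sample GWAS summary statistics with known ground truth
#'
#' Simulates the two-sample MR design: two independent cohorts are
#' drawn from the same [cohort_spec()]; per-SNP exposure associations
#' (beta, SE) come from simple regressions in the first cohort and
#' outcome associations from the second, so the instrument-exposure and
#' instrument-outcome estimates share no samples.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer; seeds for the two cohorts are derived from it.
#' @param swap_alleles if `TRUE`, the outcome table reports a random
#'   subset of SNPs on the opposite allele (labels swapped and beta
#'   negated), exercising [harmonize()]; the information content is
#'   unchanged.
#' @return List with `exposure` and `outcome` (`variant_assoc` tables)
#'   and `true_beta` (the generating causal effect).
#' @export
generate_two_sample_summary <- function(spec, seed,
                                        swap_alleles = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed)
  c1 <- generate_cohort(spec, seed = seed)
  c2 <- generate_cohort(spec, seed = seed + 500000L)
  rx <- simple_reg_by_snp(c1$exposure, c1$genotypes)
  ry <- simple_reg_by_snp(c2$outcome, c2$genotypes)
  meta <- c1$snp_meta
  exposure <- variant_assoc(rx$snp_id, meta$effect_allele,
                            meta$other_allele, rx$beta, rx$se,
                            "exposure", gene = meta$gene,
                            n = spec$n)
  ea <- meta$effect_allele
  oa <- meta$other_allele
  by <- ry$beta
  if (swap_alleles) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed + 900000L)
    flip <- stats::runif(length(by)) < 0.5
    tmp <- ea[flip]; ea[flip] <- oa[flip]; oa[flip] <- tmp
    by[flip] <- -by[flip]
  }
  outcome <- variant_assoc(ry$snp_id, ea, oa, by, ry$se, "outcome",
                           gene = meta$gene, n = spec$n)
  list(exposure = exposure, outcome = outcome,
       true_beta = spec$beta_causal)
}

#' Generate a synthetic enzyme-inhibition velocity dataset
#'
#' Evaluates the inhibition rate law on a substrate-by-inhibitor design
#' and applies multiplicative log-normal noise with coefficient of
#' variation `cv`, emulating scale-proportional laboratory velocity
#' error. Both a standard arm and a pre-incubated arm are produced; a
#' `preincubation_effect` below 1 scales down the pre-incubated arm's
#' Vmax, emulating time-dependent (mechanism-based) inactivation.
#'
#' @param params a [kinetic_params()] object (ground truth).
#' @param substrate_uM,inhibitor_uM design grids (inhibitor grid should
#'   include 0 when the dataset feeds [preincubation_test()]).
#' @param cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives exact rate-law values).
#' @param replicates replicates per design cell per arm.
#' @param preincubation_effect Vmax multiplier in (0, 1] applied to the
#'   inhibitor-containing wells of the pre-incubated arm (1 = no
#'   time-dependent inactivation; inhibitor-free reference wells are
#'   never affected).
#' @param seed integer seed.
#' @param matrix_label `"microsomes"` or `"supersomes"`, recorded on
#'   every row.
#' @return Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `velocity`, `replicate`, `preincubated`, `matrix_label`; the
#'   generating parameters are attached as attribute `"true_params"`.
#' @export
generate_kinetic_dataset <- function(params, substrate_uM,
                                     inhibitor_uM, cv = 0.05,
                                     replicates = 2L,
                                     preincubation_effect = 1,
                                     seed = 1L,
                                     matrix_label = c("microsomes",
                                                      "supersomes")) {
  stopifnot(inherits(params, "kinetic_params"))
  matrix_label <- match.arg(matrix_label)
  if (!length(substrate_uM) || !length(inhibitor_uM))
    stop("substrate and inhibitor grids must be non-empty",
         call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (preincubation_effect <= 0 || preincubation_effect > 1)
    stop("preincubation_effect must be in (0, 1]", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  grid <- expand.grid(substrate_uM = substrate_uM,
                      inhibitor_uM = inhibitor_uM,
                      replicate = seq_len(replicates),
                      preincubated = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  v <- velocity(grid$substrate_uM, grid$inhibitor_uM, params)
  # inactivation during pre-incubation requires the inhibitor to be
  # present, so the inhibitor-free reference wells are unaffected
  hit <- grid$preincubated & grid$inhibitor_uM > 0
  v[hit] <- v[hit] * preincubation_effect
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
    v <- v * noise
  }
  out <- data.frame(grid[c("substrate_uM", "inhibitor_uM")],
                    velocity = v,
                    replicate = grid$replicate,
                    preincubated = grid$preincubated,
                    matrix_label = matrix_label,
                    stringsAsFactors = FALSE)
  attr(out, "true_params") <- c(unclass(params),
                                list(cv = cv,
                                     preincubation_effect =
                                       preincubation_effect))
  out
}
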