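#' Path to a packaged summary-statistics fixture
#'
#' The package ships the published coffee-consumption GWAS summary
#' statistics (exposure) alongside outcome summary statistics for
#' cigarettes/day, plasma cotinine (SD units) and a biobank replication
#' sample, so the headline analyses run with no downloads.
#'
#' @param name one of `"ccgc_exposure"`, `"tag_outcome"`,
#'   `"cotinine_outcome"`, `"ukbiobank_outcome"`.
#' @return Path to the tab-separated fixture file.
#' @export
mrkin_fixture <- function(name = c("ccgc_exposure", "tag_outcome",
                                   "cotinine_outcome",
                                   "ukbiobank_outcome")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "mrkin", mustWork = TRUE)
  path
}

#' Load and harmonize a packaged exposure/outcome pair
#'
#' @param outcome one of `"tag"`, `"cotinine"`, `"ukbiobank"`.
#' @return A harmonized `instrument_set` covering all eight SNPs.
#' @export
load_fixture_set <- function(outcome = c("tag", "cotinine",
                                         "ukbiobank")) {
  outcome <- match.arg(outcome)
  exp_tab <- read_summary_stats(mrkin_fixture("ccgc_exposure"),
                                "exposure")
  out_tab <- read_summary_stats(
    mrkin_fixture(paste0(outcome, "_outcome")), "outcome")
  harmonize(exp_tab, out_tab)
}

provenance_block <- function(config, inputs) {
  list(package = "mrkin",
       version = as.character(utils::packageVersion("mrkin")),
       config = config,
       input_md5 = as.list(tools::md5sum(inputs)))
}

result_to_list <- function(res) {
  list(estimate = res$estimate, se = res$se, ci_low = res$ci_low,
       ci_high = res$ci_high, p = res$p, method = res$method,
       n_snps = res$n_snps)
}

#' Two-sample MR analysis of coffee consumption and smoking heaviness
#'
#' Runs the full two-sample analysis on the packaged summary
#' statistics: fixed-effects IVW estimates for the 8-, 6- and 2-SNP
#' instrument models against both the cigarettes/day and the cotinine
#' outcome, plus the weighted-median sensitivity analysis on the
#' eight-SNP cigarettes/day instrument.
#'
#' @param seed bootstrap seed for the weighted median (required; no
#'   wall-clock seeding).
#' @param n_boot weighted-median bootstrap replicates.
#' @param exposure_path,smoking_path,cotinine_path input tables;
#'   default to the packaged fixtures.
#' @param output_dir optional directory: when given, a JSON results
#'   document and one forest TSV per result are written there.
#' @return List with `results` (named `mr_result` list), `forest`
#'   (named list of forest tables) and `provenance`.
#' @export
run_study1 <- function(seed, n_boot = 1000L,
                       exposure_path = mrkin_fixture("ccgc_exposure"),
                       smoking_path = mrkin_fixture("tag_outcome"),
                       cotinine_path = mrkin_fixture("cotinine_outcome"),
                       output_dir = NULL) {
  if (missing(seed))
    stop("an explicit seed is required (no wall-clock seeding)",
         call. = FALSE)
  exp_tab <- read_summary_stats(exposure_path, "exposure")
  smoke <- harmonize(exp_tab, read_summary_stats(smoking_path,
                                                 "outcome"))
  cotinine <- harmonize(exp_tab, read_summary_stats(cotinine_path,
                                                    "outcome"))
  results <- c(
    stats::setNames(
      run_two_sample_mr(smoke, models = c("8-SNP", "6-SNP", "2-SNP"),
                        methods = "IVW-FE"),
      paste0("smoking/", c("8-SNP", "6-SNP", "2-SNP"), "/IVW-FE")),
    stats::setNames(
      run_two_sample_mr(smoke, models = "8-SNP",
                        methods = "weighted-median",
                        n_boot = n_boot, seed = seed),
      "smoking/8-SNP/weighted-median"),
    stats::setNames(
      run_two_sample_mr(cotinine,
                        models = c("8-SNP", "6-SNP", "2-SNP"),
                        methods = "IVW-FE"),
      paste0("cotinine/", c("8-SNP", "6-SNP", "2-SNP"), "/IVW-FE"))
  )
  forest <- lapply(results, forest_table)
  prov <- provenance_block(
    config = list(seed = seed, n_boot = n_boot, delta_order = "first"),
    inputs = c(exposure_path, smoking_path, cotinine_path))
  out <- list(results = results, forest = forest, provenance = prov)
  if (!is.null(output_dir)) write_results(out, output_dir, "study1")
  out
}

#' One-sample MR replication analysis
#'
#' Two analyses mirroring the biobank replication: (1) a
#' two-sample-style IVW combination of Wald ratios built from the
#' packaged exposure weights and the packaged biobank outcome
#' associations; (2) the full one-sample pipeline on a synthetic
#' cohort with known causal effect - genetic risk score, instrument
#' strength, observational regression with robust standard errors, and
#' per-SNP Wald ratios combined by IVW.
#'
#' @param seed integer seed for the synthetic cohort (required).
#' @param spec `cohort_spec` for the synthetic arm; defaults to the
#'   package's coffee-and-smoking emulation with n = 8072.
#' @param covariates covariates to adjust the synthetic-arm
#'   regressions for.
#' @param output_dir optional output directory, as in [run_study1()].
#' @return List with `fixture_ivw` (an `mr_result`), `synthetic`
#'   (list: `grs_strength`, `observational`, `mr`, `true_beta`) and
#'   `provenance`.
#' @export
run_study3 <- function(seed, spec = cohort_spec(),
                       covariates = c("age", "sex"),
                       output_dir = NULL) {
  if (missing(seed))
    stop("an explicit seed is required (no wall-clock seeding)",
         call. = FALSE)
  set <- load_fixture_set("ukbiobank")
  fixture_ivw <- run_two_sample_mr(set, models = "8-SNP",
                                   methods = "IVW-FE")[[1L]]
  cohort <- filter_analysis_sample(generate_cohort(spec, seed = seed))
  scores <- compute_grs(cohort)
  strength <- instrument_strength(
    scores, cohort$exposure,
    build_covariate_matrix(cohort, covariates))
  obs <- observational_association(cohort, covariates)
  mr <- one_sample_mr(cohort, covariates)
  prov <- provenance_block(
    config = list(seed = seed, covariates = covariates,
                  n = spec$n),
    inputs = c(mrkin_fixture("ccgc_exposure"),
               mrkin_fixture("ukbiobank_outcome")))
  out <- list(fixture_ivw = fixture_ivw,
              synthetic = list(grs_strength = strength,
                               observational = obs, mr = mr,
                               true_beta = spec$beta_causal),
              provenance = prov)
  if (!is.null(output_dir)) {
    doc <- list(fixture_ivw = result_to_list(fixture_ivw),
                synthetic = list(
                  grs_strength = strength,
                  observational = obs,
                  mr = result_to_list(mr),
                  true_beta = spec$beta_causal),
                provenance = out$provenance)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(doc, file.path(output_dir, "study3.json"),
                         auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    utils::write.table(forest_table(fixture_ivw),
                       file.path(output_dir, "study3_forest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

write_results <- function(out, output_dir, stem) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(results = lapply(out$results, result_to_list),
              provenance = out$provenance)
  jsonlite::write_json(doc, file.path(output_dir,
                                      paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(out$forest)) {
    fn <- paste0(stem, "_forest_", gsub("[^A-Za-z0-9]+", "_", nm),
                 ".tsv")
    utils::write.table(out$forest[[nm]], file.path(output_dir, fn),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Reproduce the package's headline fixture-based computations
#'
#' Convenience wrapper running the two-sample analyses on the packaged
#' tables, the biobank-style IVW, the power calculations for the
#' replication design, and the fractional-inhibition predictions for
#' plasma caffeic acid.
#'
#' @param seed integer seed (weighted-median bootstrap and synthetic
#'   cohort).
#' @return Nested list of numbers, suitable for JSON serialization.
#' @export
reproduce_all <- function(seed) {
  s1 <- run_study1(seed = seed)
  s3_ivw <- run_two_sample_mr(load_fixture_set("ukbiobank"),
                              models = "8-SNP",
                              methods = "IVW-FE")[[1L]]
  list(
    two_sample = lapply(s1$results, result_to_list),
    biobank_ivw = result_to_list(s3_ivw),
    power = list(
      r2_0.005 = mr_power(8072, 0.005, 1.5, 2, 8.5),
      r2_0.01 = mr_power(8072, 0.01, 1.5, 2, 8.5)),
    caffeic_acid = list(
      plasma_uM_2to3_cups = mg_per_l_to_uM(1.11, 180.16),
      inhibition_2to3_cups = fractional_inhibition(6.16, 156),
      inhibition_3to4_cups = fractional_inhibition(7.12, 156))
  )
}
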