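#' Per-SNP Wald ratio with delta-method standard error
#'
#' The Wald ratio beta_y / beta_x is the instrumental-variable estimate
#' of the causal effect of the exposure on the outcome contributed by a
#' single SNP, in outcome units per exposure unit. Its standard error is
#' approximated by the delta method: at first order
#' `se = |se_y / beta_x|` (the exposure beta treated as fixed); at
#' second order the exposure uncertainty is propagated,
#' `se = sqrt(se_y^2/beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param beta_x,se_x exposure association and its standard error
#'   (`se_x >= 0`; it only enters at second order).
#' @param beta_y,se_y outcome association and its standard error
#'   (`se_y > 0`).
#' @param order `"first"` (default) or `"second"` delta-method order.
#' @param snp_id optional rsID carried through for reporting.
#' @return A one-row data frame of class `"wald_estimate"` with columns
#'   `snp_id`, `ratio`, `se`, `weight` (`weight = se^-2`).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y,
                       order = c("first", "second"),
                       snp_id = NA_character_) {
  order <- match.arg(order)
  if (!is.finite(beta_x) || beta_x == 0)
    stop("beta_x is zero for SNP ", snp_id,
         ": Wald ratio undefined", call. = FALSE)
  if (se_x < 0 || se_y <= 0)
    stop("standard errors must satisfy se_x >= 0 and se_y > 0",
         call. = FALSE)
  ratio <- beta_y / beta_x
  se <- switch(order,
               first = abs(se_y / beta_x),
               second = sqrt(se_y^2 / beta_x^2 +
                             beta_y^2 * se_x^2 / beta_x^4))
  out <- data.frame(snp_id = as.character(snp_id), ratio = ratio,
                    se = se, weight = se^-2,
                    stringsAsFactors = FALSE)
  class(out) <- c("wald_estimate", "data.frame")
  out
}

#' Wald ratios for every SNP of an instrument set
#'
#' @param set an `instrument_set` (see [harmonize()]).
#' @param order delta-method order passed to [wald_ratio()].
#' @return A `wald_estimate` data frame, one row per SNP, input order.
#' @export
wald_ratios <- function(set, order = c("first", "second")) {
  order <- match.arg(order)
  stopifnot(inherits(set, "instrument_set"))
  e <- set$entries
  rows <- lapply(seq_len(nrow(e)), function(i)
    wald_ratio(e$beta_x[i], e$se_x[i], e$beta_y[i], e$se_y[i],
               order = order, snp_id = e$snp_id[i]))
  out <- do.call(rbind, rows)
  class(out) <- c("wald_estimate", "data.frame")
  out
}

mr_result <- function(estimate, se, method, per_snp,
                      p = 2 * stats::pnorm(-abs(estimate / se))) {
  structure(list(
    estimate = estimate,
    se = se,
    ci_low = estimate - 1.96 * se,
    ci_high = estimate + 1.96 * se,
    p = p,
    method = method,
    n_snps = nrow(per_snp),
    per_snp = per_snp
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s causal estimate (%d SNP%s)\n", x$method, x$n_snps,
              if (x$n_snps == 1) "" else "s"))
  cat(sprintf("  beta = %.*f, se = %.*f, 95%% CI = %.*f to %.*f, p = %.3g\n",
              digits, x$estimate, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$p))
  invisible(x)
}

#' Fixed-effects inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Combines per-SNP causal estimates with weights equal to the inverse
#' squared standard errors: `estimate = sum(w r) / sum(w)` with
#' `se = sum(w)^(-1/2)`. The 95% confidence interval is
#' `estimate +/- 1.96 se` and the p-value is two-sided normal.
#'
#' @param estimates a `wald_estimate` data frame (see [wald_ratios()]).
#' @return An object of class `"mr_result"` with fields `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p`, `method`, `n_snps`, `per_snp`.
#' @export
ivw_fixed_effects <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0L)
    stop("no Wald estimates to combine", call. = FALSE)
  w <- estimates$weight
  bad <- !is.finite(w) | w <= 0
  if (any(bad))
    stop("non-finite or non-positive weight for SNP(s): ",
         paste(estimates$snp_id[bad], collapse = ", "), call. = FALSE)
  est <- sum(w * estimates$ratio) / sum(w)
  se <- sum(w)^-0.5
  mr_result(est, se, "IVW-FE", estimates)
}

weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1L]) return(r[1L])
  m <- length(r)
  if (0.5 >= p[m]) return(r[m])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Pleiotropy-robust combination of per-SNP Wald ratios: ratios are
#' sorted, normalized cumulative mid-weights
#' `p_j = (sum_{i<=j} w_i - w_j/2) / sum(w)` are formed, and the
#' estimate is the linear interpolation of (p, ratio) at p = 0.5. It is
#' consistent when at least half of the total weight comes from valid
#' instruments. The standard error is obtained by parametric bootstrap:
#' each replicate redraws `ratio_j* ~ N(ratio_j, se_j)` and recomputes
#' the weighted median; `se` is the standard deviation over replicates.
#'
#' @param estimates a `wald_estimate` data frame.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required for
#'   reproducibility).
#' @return An `"mr_result"` with `method = "weighted-median"`.
#' @export
weighted_median <- function(estimates, n_boot = 1000L, seed) {
  if (is.null(estimates) || nrow(estimates) == 0L)
    stop("no Wald estimates to combine", call. = FALSE)
  if (n_boot < 1L)
    stop("n_boot must be >= 1", call. = FALSE)
  if (missing(seed))
    stop("an explicit bootstrap seed is required", call. = FALSE)
  if (nrow(estimates) < 3L)
    warning("weighted median with fewer than 3 SNPs is fragile")
  est <- weighted_median_point(estimates$ratio, estimates$weight)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  m <- nrow(estimates)
  boot <- vapply(seq_len(n_boot), function(b) {
    r_star <- stats::rnorm(m, estimates$ratio, estimates$se)
    weighted_median_point(r_star, estimates$weight)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result(est, se, "weighted-median", estimates)
}

#' Run a two-sample Mendelian randomization analysis
#'
#' For each requested instrument model and estimator, computes per-SNP
#' Wald ratios from a harmonized instrument set and combines them.
#'
#' @param set a harmonized `instrument_set` containing all SNPs needed
#'   by the requested models.
#' @param models character vector of model labels (subset of
#'   `"8-SNP"`, `"6-SNP"`, `"2-SNP"`); use `"custom"` to analyse the set
#'   as given.
#' @param methods estimators to run: any of `"IVW-FE"`,
#'   `"weighted-median"`.
#' @param order delta-method order for the Wald-ratio standard errors.
#' @param n_boot,seed bootstrap settings for the weighted median.
#' @return A named list of `mr_result` objects keyed
#'   `"<model>/<method>"`, in request order.
#' @export
run_two_sample_mr <- function(set,
                              models = c("8-SNP", "6-SNP", "2-SNP"),
                              methods = "IVW-FE",
                              order = c("first", "second"),
                              n_boot = 1000L, seed = 1L) {
  order <- match.arg(order)
  stopifnot(inherits(set, "instrument_set"))
  results <- list()
  for (model in models) {
    sub <- if (identical(model, "custom")) set else
      select_model(set, model)
    est <- wald_ratios(sub, order = order)
    for (method in methods) {
      res <- switch(method,
                    "IVW-FE" = ivw_fixed_effects(est),
                    "weighted-median" = weighted_median(est, n_boot,
                                                        seed),
                    stop("unknown method: ", method, call. = FALSE))
      results[[paste(model, method, sep = "/")]] <- res
    }
  }
  results
}

#' Forest-plot table for an MR result
#'
#' Emits the per-SNP rows (ratio and 95% CI) followed by a combined row,
#' the tabular equivalent of a forest plot.
#'
#' @param result an `mr_result` carrying per-SNP estimates.
#' @return A data frame with columns `snp_id`, `estimate`, `ci_low`,
#'   `ci_high`; per-SNP rows in input order, final row labelled
#'   `"combined"`.
#' @export
forest_table <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  per <- result$per_snp
  rows <- data.frame(
    snp_id = c(per$snp_id, "combined"),
    estimate = c(per$ratio, result$estimate),
    ci_low = c(per$ratio - 1.96 * per$se, result$ci_low),
    ci_high = c(per$ratio + 1.96 * per$se, result$ci_high),
    stringsAsFactors = FALSE
  )
  rows
}
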