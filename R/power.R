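#' Analytic power for a Mendelian randomization design
#'
#' Power of a two-sided test of a causal effect in an MR design with a
#' continuous exposure and outcome, using the normal approximation. The
#' standardized effect is `b = beta * sd_x / sd_y`, the non-centrality
#' parameter `NCP = n * r_squared * b^2`, and
#' `power = Phi(sqrt(NCP) - z) + Phi(-sqrt(NCP) - z)` with
#' `z = qnorm(1 - alpha/2)`. The far-tail term makes the size exact at
#' `beta = 0` (power equals `alpha`).
#'
#' @param n analysis sample size.
#' @param r_squared fraction of exposure variance explained by the
#'   instrument, in (0, 1).
#' @param beta causal effect to detect, in outcome units per exposure
#'   unit.
#' @param sd_x,sd_y standard deviations of exposure and outcome.
#' @param alpha two-sided significance level (default 0.05).
#' @return Power as a fraction in (0, 1).
#' @export
mr_power <- function(n, r_squared, beta, sd_x, sd_y, alpha = 0.05) {
  if (!is.numeric(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(r_squared) || r_squared <= 0 || r_squared >= 1)
    stop("r_squared must be in (0, 1)", call. = FALSE)
  if (sd_x <= 0 || sd_y <= 0)
    stop("sd_x and sd_y must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  b <- beta * sd_x / sd_y
  ncp <- n * r_squared * b^2
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}

#' Power curve over a grid of one design parameter
#'
#' @param n,r_squared,beta,sd_x,sd_y,alpha baseline design (see
#'   [mr_power()]).
#' @param vary name of the parameter to vary: one of `"n"`,
#'   `"r_squared"`, `"beta"`, `"sd_x"`, `"sd_y"`, `"alpha"`.
#' @param grid numeric vector of values for the varied parameter.
#' @return Data frame with columns `value` and `power`, one row per
#'   grid point.
#' @export
mr_power_curve <- function(n, r_squared, beta, sd_x, sd_y,
                           alpha = 0.05, vary, grid) {
  vary <- match.arg(vary, c("n", "r_squared", "beta", "sd_x", "sd_y",
                            "alpha"))
  base <- list(n = n, r_squared = r_squared, beta = beta,
               sd_x = sd_x, sd_y = sd_y, alpha = alpha)
  power <- vapply(grid, function(v) {
    args <- base
    args[[vary]] <- v
    do.call(mr_power, args)
  }, numeric(1))
  data.frame(value = grid, power = power)
}
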