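#' Kinetic parameters for an enzyme-inhibition model
#'
#' Describes Michaelis-Menten kinetics with a reversible inhibitor
#' acting through a competitive component (inhibition constant `ki_c`,
#' binding the free enzyme) and/or an uncompetitive component (`ki_u`,
#' binding the enzyme-substrate complex). An infinite constant switches
#' the corresponding component off:
#' \itemize{
#'   \item competitive: `ki_c` finite, `ki_u = Inf`
#'   \item uncompetitive: `ki_c = Inf`, `ki_u` finite
#'   \item noncompetitive: `ki_c = ki_u`, finite
#'   \item mixed: both finite, unequal
#' }
#'
#' @param vmax maximal velocity (e.g. nmol/min per mg protein for
#'   microsomes, nmol/min per pmol enzyme for recombinant enzyme).
#' @param km Michaelis constant (uM).
#' @param model inhibition type; determines how `ki_c`/`ki_u` are
#'   interpreted and validated.
#' @param ki_c,ki_u inhibition constants (uM), possibly `Inf`.
#' @return An object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(vmax, km,
                           model = c("competitive", "uncompetitive",
                                     "noncompetitive", "mixed"),
                           ki_c = Inf, ki_u = Inf) {
  model <- match.arg(model)
  if (vmax <= 0 || km <= 0)
    stop("vmax and km must be > 0", call. = FALSE)
  if (ki_c <= 0 || ki_u <= 0)
    stop("ki_c and ki_u must be > 0 (possibly Inf)", call. = FALSE)
  ok <- switch(model,
               competitive = is.finite(ki_c) && is.infinite(ki_u),
               uncompetitive = is.infinite(ki_c) && is.finite(ki_u),
               noncompetitive = is.finite(ki_c) && ki_c == ki_u,
               mixed = is.finite(ki_c) && is.finite(ki_u) &&
                 ki_c != ki_u)
  if (!ok)
    stop("ki_c/ki_u pattern inconsistent with model '", model, "'",
         call. = FALSE)
  structure(list(vmax = vmax, km = km, ki_c = ki_c, ki_u = ki_u,
                 model = model),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("%s inhibition: Vmax = %g, Km = %g uM, Ki(c) = %g, Ki(u) = %g\n",
              x$model, x$vmax, x$km, x$ki_c, x$ki_u))
  invisible(x)
}

#' Reaction velocity under reversible inhibition
#'
#' General mixed-inhibition rate law
#' `v = vmax * S / (km * (1 + I/ki_c) + S * (1 + I/ki_u))`;
#' infinite inhibition constants drop the corresponding term, recovering
#' the competitive, uncompetitive and plain Michaelis-Menten limits.
#'
#' @param substrate_uM substrate concentration(s), > 0.
#' @param inhibitor_uM inhibitor concentration(s), >= 0.
#' @param params a [kinetic_params()] object.
#' @return Velocity, recycled over the inputs.
#' @export
velocity <- function(substrate_uM, inhibitor_uM, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(substrate_uM <= 0))
    stop("substrate_uM must be > 0", call. = FALSE)
  if (any(inhibitor_uM < 0))
    stop("inhibitor_uM must be >= 0", call. = FALSE)
  params$vmax * substrate_uM /
    (params$km * (1 + inhibitor_uM / params$ki_c) +
       substrate_uM * (1 + inhibitor_uM / params$ki_u))
}

check_kinetic_data <- function(data, arm = c("standard", "preincubated",
                                             "all")) {
  arm <- match.arg(arm)
  needed <- c("substrate_uM", "inhibitor_uM", "velocity")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("kinetic data missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if ("preincubated" %in% names(data) && arm != "all") {
    data <- data[data$preincubated == (arm == "preincubated"), ,
                 drop = FALSE]
  }
  if (any(data$velocity <= 0))
    stop("velocities must be > 0 for linearized fits", call. = FALSE)
  s_levels <- sort(unique(data$substrate_uM))
  if (length(s_levels) < 2L)
    stop("at least 2 distinct substrate levels required", call. = FALSE)
  for (s in s_levels) {
    if (length(unique(data$inhibitor_uM[data$substrate_uM == s])) < 3L)
      stop("at least 3 distinct inhibitor levels required per substrate",
           call. = FALSE)
  }
  data
}

# Per-substrate OLS of y on inhibitor concentration; returns one line
# per substrate level with slope/intercept and their standard errors.
fit_lines <- function(data, transform) {
  s_levels <- sort(unique(data$substrate_uM))
  out <- lapply(s_levels, function(s) {
    d <- data[data$substrate_uM == s, ]
    y <- transform(d)
    fit <- stats::lm(y ~ d$inhibitor_uM)
    # exact (noise-free) data triggers a harmless perfect-fit warning
    cf <- suppressWarnings(summary(fit)$coefficients)
    data.frame(substrate_uM = s,
               intercept = cf[1L, 1L], slope = cf[2L, 1L],
               se_intercept = cf[1L, 2L], se_slope = cf[2L, 2L])
  })
  do.call(rbind, out)
}

# Parallel-line decision. Exact (noise-free) geometry is settled by the
# relative spread of the fitted slopes; otherwise a joint common-slope
# ANCOVA F-test compares one-slope-per-level against a shared slope, and
# the lines are declared parallel unless the slopes differ at level
# alpha_par.
lines_parallel <- function(data, y, lines, rel_tol = 0.02,
                           alpha_par = 0.01) {
  spread <- (max(lines$slope) - min(lines$slope)) /
    max(abs(lines$slope))
  if (spread < rel_tol) return(TRUE)
  s <- factor(data$substrate_uM)
  fit_free <- stats::lm(y ~ s + s:data$inhibitor_uM)
  fit_common <- stats::lm(y ~ s + data$inhibitor_uM)
  rss_free <- sum(stats::residuals(fit_free)^2)
  rss_common <- sum(stats::residuals(fit_common)^2)
  if (rss_free <= 1e-12 * sum(y^2)) {
    # exact fit: parallel only if the common-slope model is also exact
    return(rss_common <= 1e-12 * sum(y^2))
  }
  df_extra <- nlevels(s) - 1L
  df_res <- stats::df.residual(fit_free)
  f <- ((rss_common - rss_free) / df_extra) / (rss_free / df_res)
  p <- stats::pf(f, df_extra, df_res, lower.tail = FALSE)
  p > alpha_par
}

pairwise_intersections <- function(lines) {
  n <- nrow(lines)
  xs <- c(); ys <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ds <- lines$slope[i] - lines$slope[j]
      if (ds == 0) next
      x <- (lines$intercept[j] - lines$intercept[i]) / ds
      y <- lines$intercept[i] + lines$slope[i] * x
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  list(i_coord = stats::median(xs), y_coord = stats::median(ys))
}

#' Dixon-plot estimation of the inhibition constant
#'
#' For each substrate level, fits an ordinary least-squares line of
#' `1/velocity` against inhibitor concentration. For inhibition with a
#' competitive component the lines intersect at `I = -Ki(c)` (with
#' `y = 1/vmax` for pure competitive inhibition); Ki is taken as minus
#' the median of the pairwise intersection abscissae. When all line
#' pairs are parallel within tolerance (the uncompetitive signature) no
#' Ki is defined and the intersection is reported as `"parallel"`.
#'
#' @param data kinetic observations: data frame with columns
#'   `substrate_uM`, `inhibitor_uM`, `velocity` (and optionally
#'   `preincubated`, `replicate`).
#' @param arm which experimental arm to fit when a `preincubated`
#'   column is present: `"standard"` (default), `"preincubated"` or
#'   `"all"`.
#' @param rel_tol relative slope-spread tolerance below which the lines
#'   are declared parallel outright (settles exact geometry).
#' @param alpha_par significance level of the joint common-slope
#'   F-test; noisy lines are declared parallel unless their slopes
#'   differ at this level (guards against calling noise-level
#'   differences an intersection).
#' @return List with `ki` (NA when parallel), `lines` (per-substrate
#'   slopes/intercepts) and `intersection` (list with `i_coord`,
#'   `y_coord`, or the string `"parallel"`).
#' @export
fit_dixon <- function(data, arm = "standard", rel_tol = 0.02,
                      alpha_par = 0.01) {
  data <- check_kinetic_data(data, arm)
  y <- 1 / data$velocity
  lines <- fit_lines(data, function(d) 1 / d$velocity)
  if (lines_parallel(data, y, lines, rel_tol, alpha_par))
    return(list(ki = NA_real_, lines = lines,
                intersection = "parallel"))
  inter <- pairwise_intersections(lines)
  list(ki = -inter$i_coord, lines = lines, intersection = inter)
}

#' Cornish-Bowden plot analysis
#'
#' Fits per-substrate lines of `substrate/velocity` against inhibitor
#' concentration. These lines intersect at `I = -Ki(u)` when an
#' uncompetitive component is present and are parallel for purely
#' competitive inhibition; for noncompetitive inhibition the
#' intersection falls on the I-axis (`y = 0`). Complements the Dixon
#' plot for classifying the inhibition type.
#'
#' @inheritParams fit_dixon
#' @return List with `ki_u` (NA when parallel), `lines` and
#'   `intersection` as in [fit_dixon()].
#' @export
fit_cornish_bowden <- function(data, arm = "standard", rel_tol = 0.02,
                               alpha_par = 0.01) {
  data <- check_kinetic_data(data, arm)
  y <- data$substrate_uM / data$velocity
  lines <- fit_lines(data, function(d) d$substrate_uM / d$velocity)
  if (lines_parallel(data, y, lines, rel_tol, alpha_par))
    return(list(ki_u = NA_real_, lines = lines,
                intersection = "parallel"))
  inter <- pairwise_intersections(lines)
  list(ki_u = -inter$i_coord, lines = lines, intersection = inter)
}

#' Classify the inhibition type from Dixon and Cornish-Bowden geometry
#'
#' Combines the two linearizations into the classical decision rule:
#' \itemize{
#'   \item Dixon lines intersect, Cornish-Bowden parallel: competitive
#'     (Ki from the Dixon intersection).
#'   \item Dixon parallel, Cornish-Bowden intersects: uncompetitive
#'     (Ki from the Cornish-Bowden intersection).
#'   \item Both intersect, Cornish-Bowden intersection on the I-axis
#'     (within tolerance): noncompetitive.
#'   \item Both intersect off-axis: mixed.
#'   \item Both parallel: "undetermined" (returned with diagnostics,
#'     not an error).
#' }
#'
#' @inheritParams fit_dixon
#' @param y_rel_tol the Cornish-Bowden intersection is "on the axis"
#'   when its |y| is below this fraction of the median Cornish-Bowden
#'   intercept magnitude.
#' @return An object of class `"inhibition_fit"`: list with `ki`,
#'   `ki_u`, `inferred_type`, `dixon_lines`, `cb_lines`,
#'   `dixon_intersection`, `cb_intersection`, `diagnostics`.
#' @export
classify_inhibition <- function(data, arm = "standard",
                                rel_tol = 0.02, alpha_par = 0.01,
                                y_rel_tol = 0.25) {
  dx <- fit_dixon(data, arm, rel_tol, alpha_par)
  cb <- fit_cornish_bowden(data, arm, rel_tol, alpha_par)
  dx_par <- identical(dx$intersection, "parallel")
  cb_par <- identical(cb$intersection, "parallel")
  ki <- NA_real_; ki_u <- NA_real_
  if (dx_par && cb_par) {
    type <- "undetermined"
  } else if (!dx_par && cb_par) {
    type <- "competitive"
    ki <- dx$ki
  } else if (dx_par && !cb_par) {
    type <- "uncompetitive"
    ki_u <- cb$ki_u
  } else {
    y_scale <- stats::median(abs(cb$lines$intercept))
    if (abs(cb$intersection$y_coord) <= y_rel_tol * y_scale) {
      type <- "noncompetitive"
      ki <- dx$ki
      ki_u <- cb$ki_u
    } else {
      type <- "mixed"
      ki <- dx$ki
      ki_u <- cb$ki_u
    }
  }
  structure(list(
    ki = ki, ki_u = ki_u, inferred_type = type,
    dixon_lines = dx$lines, cb_lines = cb$lines,
    dixon_intersection = dx$intersection,
    cb_intersection = cb$intersection,
    diagnostics = list(dixon_parallel = dx_par, cb_parallel = cb_par)
  ), class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Inhibition type: %s", x$inferred_type))
  if (is.finite(x$ki)) cat(sprintf("; Ki = %.3g uM", x$ki))
  if (is.finite(x$ki_u)) cat(sprintf("; Ki(u) = %.3g uM", x$ki_u))
  cat("\n")
  invisible(x)
}

#' Test for mechanism-based (irreversible) inhibition by pre-incubation
#'
#' A mechanism-based inhibitor is metabolically activated by the enzyme
#' and inactivates it irreversibly, so pre-incubating enzyme with
#' inhibitor before adding substrate lowers the remaining activity
#' relative to co-incubation. For each arm the percent activity
#' remaining at each inhibitor concentration is
#' `100 * v(I) / v(0)` (velocities averaged over replicates and
#' substrate levels); the verdict is `"mechanism-based-candidate"` when
#' the pre-incubated arm is significantly lower by a one-sided paired
#' t-test across inhibitor concentrations.
#'
#' @param data kinetic observations containing both arms (logical
#'   column `preincubated`), on matched substrate/inhibitor grids.
#' @param alpha one-sided significance level (default 0.05).
#' @return List with `verdict`, `p_value`, and `activity`: a data frame
#'   of percent activity remaining per inhibitor concentration and arm.
#' @export
preincubation_test <- function(data, alpha = 0.05) {
  needed <- c("substrate_uM", "inhibitor_uM", "velocity", "preincubated")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("preincubation data missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  grid0 <- unique(data[!data$preincubated,
                       c("substrate_uM", "inhibitor_uM")])
  grid1 <- unique(data[data$preincubated,
                       c("substrate_uM", "inhibitor_uM")])
  key <- function(g) sort(paste(g$substrate_uM, g$inhibitor_uM))
  if (!identical(key(grid0), key(grid1)))
    stop("pre-incubated and standard arms must share the same ",
         "substrate/inhibitor grid", call. = FALSE)
  pct_remaining <- function(d) {
    v <- stats::aggregate(velocity ~ inhibitor_uM, data = d, FUN = mean)
    v0 <- v$velocity[v$inhibitor_uM == 0]
    if (!length(v0))
      stop("each arm needs inhibitor concentration 0 as reference",
           call. = FALSE)
    data.frame(inhibitor_uM = v$inhibitor_uM,
               pct_activity = 100 * v$velocity / v0)
  }
  a0 <- pct_remaining(data[!data$preincubated, ])
  a1 <- pct_remaining(data[data$preincubated, ])
  m <- merge(a0, a1, by = "inhibitor_uM",
             suffixes = c("_standard", "_preincubated"))
  m <- m[m$inhibitor_uM > 0, , drop = FALSE]
  diffs <- m$pct_activity_standard - m$pct_activity_preincubated
  if (length(diffs) < 1L)
    stop("no non-zero inhibitor concentrations to compare",
         call. = FALSE)
  if (all(diffs == 0) || stats::sd(diffs) == 0) {
    p <- if (mean(diffs) > 0) 0 else 1
  } else {
    p <- stats::t.test(diffs, alternative = "greater")$p.value
  }
  verdict <- if (is.finite(p) && p < alpha)
    "mechanism-based-candidate" else "not-mechanism-based"
  list(verdict = verdict, p_value = p, activity = m)
}

#' Predicted fractional inhibition at a physiological concentration
#'
#' Fraction by which a competitive inhibitor at concentration `I`
#' reduces the reaction rate. In the low-substrate limit (substrate far
#' below Km, the default) this is `I / (I + Ki)`; when substrate and Km
#' are supplied the full competitive rate law is used:
#' `1 - v(S, I) / v(S, 0)`.
#'
#' @param inhibitor_uM inhibitor concentration (uM, >= 0).
#' @param ki_uM inhibition constant (uM, > 0).
#' @param substrate_uM,km_uM optional substrate concentration and
#'   Michaelis constant; both or neither must be given.
#' @return Fraction of activity inhibited, in [0, 1).
#' @export
fractional_inhibition <- function(inhibitor_uM, ki_uM,
                                  substrate_uM = NULL, km_uM = NULL) {
  if (any(ki_uM <= 0)) stop("ki_uM must be > 0", call. = FALSE)
  if (any(inhibitor_uM < 0))
    stop("inhibitor_uM must be >= 0", call. = FALSE)
  if (is.null(substrate_uM)) {
    return(inhibitor_uM / (inhibitor_uM + ki_uM))
  }
  if (is.null(km_uM))
    stop("km_uM is required when substrate_uM is given", call. = FALSE)
  1 - (km_uM + substrate_uM) /
    (km_uM * (1 + inhibitor_uM / ki_uM) + substrate_uM)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param mg_per_l concentration in mg/l (>= 0).
#' @param mw_g_per_mol molecular weight in g/mol (> 0).
#' @return Concentration in micromolar: `1000 * mg_per_l / mw`.
#' @export
mg_per_l_to_uM <- function(mg_per_l, mw_g_per_mol) {
  if (any(mw_g_per_mol <= 0))
    stop("molecular weight must be > 0", call. = FALSE)
  if (any(mg_per_l < 0))
    stop("concentration must be >= 0", call. = FALSE)
  1000 * mg_per_l / mw_g_per_mol
}
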