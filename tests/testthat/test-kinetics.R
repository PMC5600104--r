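params_of <- function(model, ki_c = Inf, ki_u = Inf, vmax = 1, km = 50)
  kinetic_params(vmax, km, model, ki_c = ki_c, ki_u = ki_u)

exact_data <- function(params, S = c(25, 100), I = c(0, 10, 20, 40))
  generate_kinetic_dataset(params, S, I, cv = 0, replicates = 1,
                           seed = 1)

test_that("the rate law recovers its classical limits", {
  comp <- params_of("competitive", ki_c = 20)
  # no inhibitor: plain Michaelis-Menten
  expect_equal(velocity(50, 0, comp), 1 * 50 / (50 + 50))
  # hand-computed point: S = Km = 50, I = Ki = 20 halves the Km term
  expect_equal(velocity(50, 20, comp), 1 / 3)
  # competitive inhibition is surmountable at saturating substrate
  expect_equal(velocity(1e12, 500, comp), 1, tolerance = 1e-6)
  # uncompetitive inhibition is not
  unc <- params_of("uncompetitive", ki_u = 20)
  expect_equal(velocity(1e12, 20, unc), 0.5, tolerance = 1e-6)
})

test_that("velocity is monotone in substrate and inhibitor", {
  models <- list(params_of("competitive", ki_c = 20),
                 params_of("uncompetitive", ki_u = 30),
                 params_of("noncompetitive", ki_c = 25, ki_u = 25),
                 params_of("mixed", ki_c = 21, ki_u = 60))
  S <- seq(5, 200, length.out = 10)
  I <- seq(0, 100, length.out = 10)
  for (p in models) {
    expect_true(all(diff(velocity(S, 10, p)) > 0))
    expect_true(all(diff(velocity(50, I, p)) < 0))
  }
})

test_that("kinetic parameter patterns are validated per model", {
  expect_error(kinetic_params(1, 50, "competitive"), "inconsistent")
  expect_error(kinetic_params(1, 50, "noncompetitive", ki_c = 20,
                              ki_u = 30), "inconsistent")
  expect_error(kinetic_params(1, 50, "mixed", ki_c = 20, ki_u = 20),
               "inconsistent")
  expect_error(kinetic_params(0, 50, "competitive", ki_c = 20), "vmax")
  expect_error(velocity(-1, 0, params_of("competitive", ki_c = 20)))
})

test_that("Dixon geometry matches closed forms on exact data", {
  # competitive: lines cross at (-Ki, 1/Vmax)
  d <- exact_data(params_of("competitive", ki_c = 20))
  fit <- fit_dixon(d)
  expect_equal(fit$ki, 20, tolerance = 1e-9)
  expect_equal(fit$intersection$i_coord, -20, tolerance = 1e-9)
  expect_equal(fit$intersection$y_coord, 1, tolerance = 1e-9)

  # mixed: intersection y = (1 - ki_c/ki_u)/vmax
  dm <- exact_data(params_of("mixed", ki_c = 21, ki_u = 60))
  fm <- fit_dixon(dm)
  expect_equal(fm$intersection$i_coord, -21, tolerance = 1e-9)
  expect_equal(fm$intersection$y_coord, (1 - 21 / 60) / 1,
               tolerance = 1e-9)

  # uncompetitive: slopes are substrate-independent, lines parallel
  du <- exact_data(params_of("uncompetitive", ki_u = 30))
  fu <- fit_dixon(du)
  expect_identical(fu$intersection, "parallel")
  expect_true(is.na(fu$ki))
})

test_that("Cornish-Bowden geometry matches closed forms on exact data", {
  # competitive: [S]/v slope is substrate-independent -> parallel
  d <- exact_data(params_of("competitive", ki_c = 20))
  expect_identical(fit_cornish_bowden(d)$intersection, "parallel")

  # uncompetitive: lines cross at I = -ki_u
  du <- exact_data(params_of("uncompetitive", ki_u = 30))
  fu <- fit_cornish_bowden(du)
  expect_equal(fu$ki_u, 30, tolerance = 1e-9)

  # noncompetitive: intersection on the I-axis at I = -ki
  dn <- exact_data(params_of("noncompetitive", ki_c = 25, ki_u = 25))
  fn <- fit_cornish_bowden(dn)
  expect_equal(fn$intersection$i_coord, -25, tolerance = 1e-9)
  expect_equal(fn$intersection$y_coord, 0, tolerance = 1e-9)

  # mixed: intersection y = km(1 - ki_u/ki_c)/vmax
  dm <- exact_data(params_of("mixed", ki_c = 21, ki_u = 60))
  fm <- fit_cornish_bowden(dm)
  expect_equal(fm$intersection$i_coord, -60, tolerance = 1e-9)
  expect_equal(fm$intersection$y_coord, 50 * (1 - 60 / 21),
               tolerance = 1e-9)
})

test_that("the classifier round-trips all four models on exact data", {
  expect_equal(classify_inhibition(
    exact_data(params_of("competitive", ki_c = 20)))$inferred_type,
    "competitive")
  expect_equal(classify_inhibition(
    exact_data(params_of("uncompetitive", ki_u = 30)))$inferred_type,
    "uncompetitive")
  expect_equal(classify_inhibition(
    exact_data(params_of("noncompetitive", ki_c = 25,
                         ki_u = 25)))$inferred_type,
    "noncompetitive")
  expect_equal(classify_inhibition(
    exact_data(params_of("mixed", ki_c = 21, ki_u = 60)))$inferred_type,
    "mixed")
  # competitive verdict carries the Dixon Ki
  fit <- classify_inhibition(exact_data(params_of("competitive",
                                                  ki_c = 20)))
  expect_equal(fit$ki, 20, tolerance = 1e-9)
})

test_that("degenerate kinetic designs are rejected", {
  p <- params_of("competitive", ki_c = 20)
  one_s <- generate_kinetic_dataset(p, 25, c(0, 10, 20), cv = 0,
                                    replicates = 1, seed = 1)
  expect_error(fit_dixon(one_s), "substrate")
  two_i <- generate_kinetic_dataset(p, c(25, 100), c(0, 10), cv = 0,
                                    replicates = 1, seed = 1)
  expect_error(fit_dixon(two_i), "inhibitor")
})

test_that("pre-incubation comparison flags mechanism-based inhibitors", {
  p <- params_of("competitive", ki_c = 20)
  S <- c(25, 100); I <- c(0, 10, 20, 40)

  # no time-dependent loss: identical arms
  same <- generate_kinetic_dataset(p, S, I, cv = 0, replicates = 2,
                                   preincubation_effect = 1, seed = 1)
  expect_equal(preincubation_test(same)$verdict, "not-mechanism-based")

  # 40% Vmax loss in the pre-incubated arm
  tdi <- generate_kinetic_dataset(p, S, I, cv = 0.05, replicates = 3,
                                  preincubation_effect = 0.6, seed = 2)
  res <- preincubation_test(tdi)
  expect_equal(res$verdict, "mechanism-based-candidate")
  expect_true(all(res$activity$pct_activity_preincubated <
                    res$activity$pct_activity_standard))

  # activity *higher* after pre-incubation is not flagged (one-sided)
  up <- same
  up$velocity[up$preincubated] <- up$velocity[up$preincubated] * 1.2
  up$velocity[up$preincubated & up$inhibitor_uM == 0] <-
    same$velocity[same$preincubated & same$inhibitor_uM == 0]
  expect_equal(preincubation_test(up)$verdict, "not-mechanism-based")

  # mismatched grids are a design error
  broken <- same[!(same$preincubated & same$inhibitor_uM == 40), ]
  expect_error(preincubation_test(broken), "grid")
})

test_that("fractional inhibition reproduces the plasma predictions", {
  # plasma caffeic acid at 2-3 and 3-4 cups/day against Ki 156 uM
  expect_equal(round(100 * fractional_inhibition(6.16, 156), 1), 3.8)
  expect_equal(round(100 * fractional_inhibition(7.12, 156), 1), 4.4)
  expect_equal(fractional_inhibition(0, 156), 0)
  expect_error(fractional_inhibition(5, -1), "ki")

  # with substrate: tends to the low-substrate limit as S -> 0
  f_lim <- fractional_inhibition(6.16, 156)
  f_s <- fractional_inhibition(6.16, 156, substrate_uM = 50 * 1e-6,
                               km_uM = 50)
  expect_equal(f_s, f_lim, tolerance = 1e-6)
  expect_error(fractional_inhibition(6.16, 156, substrate_uM = 50),
               "km")
})

test_that("mass-to-molar conversion matches the caffeic acid figures", {
  expect_equal(round(mg_per_l_to_uM(1.11, 180.16), 2), 6.16)
  # 1.28 mg/l computes to 7.10 uM at MW 180.16 (not 7.12; the
  # conversion is reported as computed)
  expect_equal(round(mg_per_l_to_uM(1.28, 180.16), 2), 7.10)
  expect_equal(mg_per_l_to_uM(0, 180.16), 0)
  expect_error(mg_per_l_to_uM(1, 0), "molecular weight")
})
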