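# Bias regressions, calibration equations, sequential R2 decomposition, and
# prediction.

test_that("perfect agreement gives a null bias regression", {
  at <- small_table(200, seed = 31)
  # force Q = W for the FFQ energy report
  at$logq_ffq_energy <- at$logw_energy
  bf <- fit_bias(at, "ffq", "energy")
  expect_true(all(abs(bf$coefficients) < 1e-12))
  expect_lt(bf$r2_total, 1e-12)
})

test_that("fits agree with the normal-equations oracle on small instances", {
  for (seed in c(41, 42, 43)) {
    at <- tiny_table(50, seed = seed)
    fit <- fit_calibration(at, "protein", instruments = "dfr4",
                           psychosocial = FALSE)
    oracle <- ne_ols(fit$X, fit$y)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
    bf <- fit_bias(at, "hr24", "energy", psychosocial = FALSE)
    ob <- ne_ols(bf$X, bf$y)
    expect_equal(unname(bf$coefficients), unname(ob$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(bf$se), unname(ob$se), tolerance = 1e-8)
  }
})

test_that("sequential R2 decomposition telescopes and matches nested refits", {
  at <- small_table(300, seed = 32)
  for (nu in c("energy", "protein")) {
    fit <- fit_calibration(at, nu)
    dec <- r2_decompose(fit)
    expect_lt(abs(sum(dec$r2) - fit$r2_total), 1e-10)
    expect_equal(attr(dec, "r2_total"), fit$r2_total, tolerance = 1e-12)
    # independent oracle: brute-force nested lm() refits
    expect_equal(dec$r2, unname(nested_r2_oracle(fit)), tolerance = 1e-8)
    # adding a predictor group never decreases R2
    expect_true(all(dec$r2 > -1e-12))
  }
})

test_that("orthogonal predictor groups decompose order-invariantly", {
  at <- small_table(400, seed = 33)
  fit <- fit_calibration(at, "energy")
  fwd <- r2_decompose(fit)
  rev_order <- rev(names(fit$groups))
  bwd <- r2_decompose(fit, order = rev_order)
  # both orders conserve the total
  expect_equal(attr(bwd, "r2_total"), attr(fwd, "r2_total"),
               tolerance = 1e-10)
  # correlated groups reallocate between orders, but every contribution
  # stays non-negative
  expect_true(all(bwd$r2 > -1e-12))
  expect_error(r2_decompose(fit, order = c("bmi", "age")), "permutation")

  # truly orthogonal groups: contributions equal marginal R2 in any order
  set.seed(33)
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n, 0, 0.2)
  X <- cbind("(Intercept)" = 1, g1 = x1, g2 = x2)
  f <- structure(list(X = X, y = y, sst = sum((y - mean(y))^2),
                      groups = list(a = "g1", b = "g2")),
                 class = "calibfit")
  d_ab <- r2_decompose(f, c("a", "b"))
  d_ba <- r2_decompose(f, c("b", "a"))
  expect_equal(d_ab$r2[d_ab$group == "a"], d_ba$r2[d_ba$group == "a"],
               tolerance = 1e-10)
  expect_equal(d_ab$r2[d_ab$group == "b"], d_ba$r2[d_ba$group == "b"],
               tolerance = 1e-10)
})

test_that("an uninformative self-report carries no explained variance", {
  cfg <- null_psych_config(4000)
  cfg$selfreport$ffq$energy <- list(bias0 = 0, slope = 0, coefs = c(),
                                    var_r = 0.04, var_u = 0.02)
  cfg$seed <- 34L
  at <- build_analysis_table(simulate_cohort(cfg))
  fit <- fit_calibration(at, "energy", instruments = "ffq")
  sr <- fit$coefficients["log_FFQ_c"]
  expect_lt(abs(sr), 2.5 * fit$se["log_FFQ_c"])
  expect_lt(fit$r2_groups["selfreport_ffq"], 0.3)
})

test_that("calibration slope shows classical attenuation", {
  cfg <- null_psych_config(10000)
  # pure model B with slope s1 and occasion noise only
  cfg$selfreport$ffq$energy <- list(bias0 = 0, slope = 0.5, coefs = c(),
                                    var_r = 0, var_u = 0.05)
  cfg$seed <- 35L
  at <- build_analysis_table(simulate_cohort(cfg))
  fit <- fit_calibration(at, "energy", instruments = "ffq",
                         psychosocial = FALSE)
  expect_lt(fit$coefficients["log_FFQ_c"], 1 / 0.5)
  expect_gt(fit$coefficients["log_FFQ_c"], 0)
})

test_that("prediction reproduces fitted values and respects stored centers", {
  at <- small_table(250, seed = 36)
  fit <- fit_calibration(at, "energy")
  sub <- at[match(fit$ids, at$participant_id), ]
  expect_equal(predict(fit, sub), unname(fitted(fit)), tolerance = 1e-10)
  expect_equal(predict(fit), fit$fitted)
  # residuals are response minus fitted
  expect_equal(residuals(fit), fit$y - fitted(fit))
  # prediction on a shifted copy moves by beta * shift (centers are frozen)
  sub2 <- sub
  sub2$bmi <- sub2$bmi + 1
  expect_equal(predict(fit, sub2) - predict(fit, sub),
               rep(unname(fit$coefficients["bmi_c"]), nrow(sub)),
               tolerance = 1e-10)
  expect_error(predict(fit, sub[, setdiff(names(sub), "cat_meals")]),
               "cat_meals")
})

test_that("fit objects print, summarize and simulate coherently", {
  at <- small_table(200, seed = 37)
  fit <- fit_calibration(at, "protein", instruments = "ffq")
  expect_output(print(fit), "Calibration equation")
  s <- summary(fit)
  expect_s3_class(s, "summary.calibfit")
  expect_output(print(s), "Sequential R2 contributions")
  expect_equal(coef(fit), fit$coefficients)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  sims2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sims, sims2)
  bf <- fit_bias(at, "ffq", "protein")
  expect_output(print(bf), "Bias regression")
  expect_error(predict(bf, at), "calibration fits only")
})
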