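# Synthetic cohort generator: cohort structure, marginal calibration of the
# psychosocial scores, latent-intake construction, and the classical
# biomarker error model.

test_that("participant generation honors size, strata and reliability flags", {
  cfg <- cohort_config(n = 450, seed = 1)
  p <- generate_participants(cfg)
  expect_equal(nrow(p), 450)
  expect_equal(sum(p$reliability), 88)   # floor(450 * 0.196)

  p1 <- generate_participants(cohort_config(n = 1, seed = 2))
  expect_equal(nrow(p1), 1)
  expect_true(sum(p1$reliability) %in% c(0, 1))

  big <- generate_participants(cohort_config(n = 10000, seed = 3))
  props <- prop.table(table(big$race))
  expect_true(all(abs(props - cohort_config()$race_weights[names(props)])
                  < 0.02))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n = 0), "positive")
  w <- cohort_config()$race_weights
  w[1] <- w[1] + 0.1
  expect_error(cohort_config(race_weights = w), "sum to 1")
  C <- diag(6)
  C[1, 2] <- C[2, 1] <- 0.999
  C[1, 3] <- C[3, 1] <- 0.999
  C[2, 3] <- C[3, 2] <- -0.999
  dimnames(C) <- list(dietcalib:::.factors, dietcalib:::.factors)
  expect_error(cohort_config(psych_corr = C), "positive semi-definite")
  expect_error(cohort_config(rho = 1), "rho")
})

test_that("psychosocial scores reproduce configured means and correlations", {
  cfg <- cohort_config(n = 10000, seed = 42)
  p <- generate_participants(cfg)
  ps <- generate_psychosocial(p, cfg)
  # reported cohort mean for uncontrolled eating
  expect_lt(abs(mean(ps$unc) - 25.66), 0.2)
  # strongest reported correlation: uncontrolled vs emotional eating
  expect_lt(abs(cor(ps$unc, ps$emo) - 0.60), 0.05)
  # BMI is negatively associated with emotional eating by default
  expect_lt(cor(p$bmi, ps$emo), -0.3)
  # all scores stay on their instrument supports
  for (f in dietcalib:::.factors) {
    s <- dietcalib:::.factor_support[[f]]
    expect_true(all(ps[[f]] >= s[1] & ps[[f]] <= s[2]))
  }
})

test_that("identity correlation structure yields independent scores", {
  cfg <- cohort_config(n = 10000, seed = 5,
                       psych_corr = structure(
                         diag(6), dimnames = list(dietcalib:::.factors,
                                                  dietcalib:::.factors)),
                       bmi_corr = c(meals = 0, body = 0, restraint = 0,
                                    unc = 0, emo = 0, socdes = 0))
  ps <- generate_psychosocial(generate_participants(cfg), cfg)
  cors <- cor(ps[, dietcalib:::.factors])
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.03))
})

test_that("latent intake honors configured moments and the energy constraint", {
  # point mass when all variation is switched off
  cfg0 <- cohort_config(n = 50, seed = 6,
                        z_resid_sd = c(energy = 0, protein = 0),
                        z_bmi_coef = c(energy = 0, protein = 0),
                        z_age_coef = c(energy = 0, protein = 0))
  li0 <- generate_latent_intake(generate_participants(cfg0), cfg0)
  expect_true(all(li0$z_energy == cfg0$z_mean["energy"]))
  expect_true(all(li0$z_protein == cfg0$z_mean["protein"]))

  # configured BMI slope is recovered by OLS on generated data
  cfg <- cohort_config(n = 10000, seed = 7,
                       z_bmi_coef = c(energy = 0.01, protein = 0.008))
  p <- generate_participants(cfg)
  li <- generate_latent_intake(p, cfg)
  slope <- coef(lm(li$z_energy ~ p$bmi))[2]
  expect_lt(abs(slope - 0.01), 0.002)

  # protein energy below total energy everywhere
  expect_true(all(4 * exp(li$z_protein) < exp(li$z_energy)))
})

test_that("biomarkers follow the classical replicate error model", {
  # error-free biomarker reproduces the latent intake exactly
  cfg0 <- cohort_config(n = 100, seed = 8, sd_e = c(energy = 0, protein = 0),
                        reliability_fraction = 1)
  p0 <- generate_participants(cfg0)
  li0 <- generate_latent_intake(p0, cfg0)
  bm0 <- generate_biomarkers(li0, p0, cfg0)
  e0 <- bm0[bm0$nutrient == "energy", ]
  expect_equal(e0$logw1, li0$z_energy)
  expect_equal(e0$logw2, e0$logw1)

  # var(W1 - W2) = 2 sd_e^2 (1 - rho): with sd_e = 0.2, rho = 0 the
  # half-variance of the difference estimates 0.04
  cfg <- cohort_config(n = 10000, seed = 9, reliability_fraction = 1,
                       sd_e = c(energy = 0.2, protein = 0.2))
  p <- generate_participants(cfg)
  li <- generate_latent_intake(p, cfg)
  bm <- generate_biomarkers(li, p, cfg)
  en <- bm[bm$nutrient == "energy", ]
  expect_lt(abs(var(en$logw1 - en$logw2) / 2 - 0.04), 0.003)

  # corr(W1, W2) = (var Z + rho sd_e^2) / (var Z + sd_e^2)
  cfg2 <- cohort_config(n = 10000, seed = 10, reliability_fraction = 1,
                        sd_e = c(energy = 0.2, protein = 0.2), rho = -0.1)
  p2 <- generate_participants(cfg2)
  li2 <- generate_latent_intake(p2, cfg2)
  bm2 <- generate_biomarkers(li2, p2, cfg2)
  en2 <- bm2[bm2$nutrient == "energy", ]
  vz <- var(li2$z_energy)
  expected <- (vz + (-0.1) * 0.04) / (vz + 0.04)
  expect_lt(abs(cor(en2$logw1, en2$logw2) - expected), 0.02)
})

test_that("self-report model reduces correctly in its degenerate corners", {
  cfg <- cohort_config(n = 300, seed = 11)
  # unbiased noiseless reporter: Q = Z exactly
  for (ins in names(cfg$selfreport))
    for (nu in names(cfg$selfreport[[ins]]))
      cfg$selfreport[[ins]][[nu]] <- list(bias0 = 0, slope = 1,
                                          coefs = c(), var_r = 0, var_u = 0)
  p <- generate_participants(cfg)
  ps <- generate_psychosocial(p, cfg)
  li <- generate_latent_intake(p, cfg)
  sr <- generate_self_reports(li, p, ps, cfg)
  ffq_e <- sr[sr$instrument == "ffq" & sr$nutrient == "energy", ]
  expect_equal(ffq_e$logq, li$z_energy)

  # no-signal reporter: Q constant within covariate pattern
  cfg$selfreport$ffq$energy <- list(bias0 = 0.3, slope = 0,
                                    coefs = c(socdes_H = 0.5),
                                    var_r = 0, var_u = 0)
  sr2 <- generate_self_reports(li, p, ps, cfg)
  q2 <- sr2[sr2$instrument == "ffq" & sr2$nutrient == "energy", "logq"]
  sd_h <- categorize(ps$socdes, printed_cutoffs()$socdes) == "H"
  expect_equal(length(unique(round(q2[sd_h], 12))), 1)
  expect_equal(length(unique(round(q2[!sd_h], 12))), 1)
  expect_equal(unique(q2[sd_h]) - unique(q2[!sd_h]), 0.5)

  # unknown covariate names in the bias coefficients are rejected
  cfg$selfreport$ffq$energy$coefs <- c(nonexistent = 1)
  expect_error(validate_config <- dietcalib:::validate_config(cfg),
               "unknown self-report covariate")
})

test_that("identical config and seed reproduce byte-identical cohorts", {
  cfg <- cohort_config(n = 120, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  for (el in c("participants", "psychosocial", "intake_truth",
               "biomarkers", "selfreports"))
    expect_identical(c1[[el]], c2[[el]])

  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # round trip through CSV preserves the log-scale tables
  back <- read_cohort(d1)
  expect_equal(back$biomarkers$logw1, c1$biomarkers$logw1, tolerance = 1e-12)
  expect_equal(back$selfreports$logq, c1$selfreports$logq, tolerance = 1e-12)
})
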