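# Instrument scoring and low/medium/high categorization.

test_that("Crowne-Marlowe scoring counts keyed responses and classifies", {
  expect_equal(score_social_desirability(rep(TRUE, 33)),
               list(score = 33, class = "high"))
  expect_equal(score_social_desirability(rep(FALSE, 33)),
               list(score = 0, class = "low"))
  # 21 keyed responses fall in the published high band (20-33)
  items <- c(rep(TRUE, 21), rep(FALSE, 12))
  expect_equal(score_social_desirability(items)$score, 21)
  expect_equal(score_social_desirability(items)$class, "high")
  # reverse-keyed items count when the response matches the key
  key <- rep(c(TRUE, FALSE), length.out = 33)
  expect_equal(score_social_desirability(!key, key)$score, 0)
  expect_equal(score_social_desirability(key, key)$score, 33)
  expect_error(score_social_desirability(rep(TRUE, 32)), "33")
  expect_error(score_social_desirability(c(rep(TRUE, 32), NA)), "33")
})

test_that("TFEQ-R18 scale scores are sums over the 6/9/3 item mapping", {
  expect_equal(score_tfeq(rep(1L, 18)),
               c(restraint = 6, unc = 9, emo = 3))
  expect_equal(score_tfeq(rep(4L, 18)),
               c(restraint = 24, unc = 36, emo = 12))
  expect_error(score_tfeq(c(rep(1L, 17), 5L)), "1..4")
  expect_error(score_tfeq(rep(1L, 17)), "18")
})

test_that("scoring is invariant under item permutation with a matched key", {
  set.seed(4)
  items <- sample(c(TRUE, FALSE), 33, replace = TRUE)
  key <- sample(c(TRUE, FALSE), 33, replace = TRUE)
  perm <- sample(33)
  expect_equal(score_social_desirability(items, key)$score,
               score_social_desirability(items[perm], key[perm])$score)
  tf <- sample(1:4, 18, replace = TRUE)
  mp <- tfeq_default_mapping()
  perm18 <- sample(18)
  expect_equal(score_tfeq(tf, mp), score_tfeq(tf[perm18], mp[perm18]))
})

test_that("body-image discordance is the signed perceived-minus-ideal gap", {
  expect_equal(body_image_discordance(5, 4), 1)
  expect_equal(body_image_discordance(6, 6), 0)
  expect_equal(body_image_discordance(9, 5), 4)
  expect_equal(body_image_discordance(2, 7), -5)
  expect_error(body_image_discordance(10, 5), "1..9")
  # the fixed <1 / 1-2 / >=3 scheme
  co <- printed_cutoffs()$body
  expect_equal(as.character(categorize(c(0, -3, 1, 2, 3, 4), co)),
               c("L", "L", "M", "M", "H", "H"))
})

test_that("percent of meals at home filters by instrument", {
  rec <- data.frame(
    participant_id = c(rep(1, 14), rep(2, 3)),
    at_home = c(rep(TRUE, 10), FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    instrument = c(rep("4DFR", 12), rep("24HR", 2), rep("4DFR", 3)))
  pm <- percent_meals_home(rec, "4DFR")
  expect_equal(pm$pct_meals_home[pm$participant_id == 1], 100 * 10 / 12)
  expect_equal(pm$pct_meals_home[pm$participant_id == 2], 100)
  # participant with only 24HR records is missing under the 4DFR filter
  rec2 <- rbind(rec, data.frame(participant_id = 3, at_home = TRUE,
                                instrument = "24HR"))
  pm2 <- percent_meals_home(rec2, "4DFR")
  expect_true(is.na(pm2$pct_meals_home[pm2$participant_id == 3]))
  # all meals at home
  all_home <- data.frame(participant_id = 1, at_home = rep(TRUE, 12),
                         instrument = "4DFR")
  expect_equal(percent_meals_home(all_home)$pct_meals_home, 100)
})

test_that("categorization applies the printed cut-offs with <= boundaries", {
  co <- printed_cutoffs()
  expect_equal(as.character(categorize(c(19, 20, 24, 25), co$socdes)),
               c("L", "M", "M", "H"))
  expect_equal(as.character(categorize(c(79.6, 92.3, 92.31), co$meals)),
               c("L", "M", "H"))
  expect_equal(as.character(categorize(c(7, 10, 11), co$emo)),
               c("L", "M", "H"))
  expect_equal(as.character(categorize(c(14, 15, 16, 17), co$restraint)),
               c("L", "M", "M", "H"))
  expect_equal(as.character(categorize(c(24, 25, 27, 28), co$unc)),
               c("L", "M", "M", "H"))
  expect_error(categorize(1:5, c(3, 2)), "ordered")
  # missing scores stay missing; categories partition the non-missing rest
  x <- c(NA, 1, 19, 20, 24, 25, 33)
  cat3 <- categorize(x, co$socdes)
  expect_true(is.na(cat3[1]))
  expect_equal(sum(table(cat3)), sum(!is.na(x)))
})

test_that("empirical tertiles use the inverse-CDF quantile", {
  expect_equal(unname(compute_tertile_cutoffs(1:9)), c(3, 6))
  g <- categorize(1:9, compute_tertile_cutoffs(1:9))
  expect_equal(as.numeric(table(g)), c(3, 3, 3))
  expect_error(compute_tertile_cutoffs(rep(5, 10)), "distinct")
  set.seed(12)
  u <- runif(9999)
  q <- compute_tertile_cutoffs(u)
  expect_lt(abs(q[1] - 1 / 3), 0.02)
  expect_lt(abs(q[2] - 2 / 3), 0.02)
  # tertile cut-offs + categorize give near-equal groups up to ties
  g2 <- table(categorize(u, q))
  expect_true(max(g2) - min(g2) <= 2)
})

test_that("raw response tables score into the six-factor table", {
  resp <- data.frame(participant_id = 1:2, perceived = c(5, 4),
                     ideal_self = c(4, 4))
  for (i in 1:33) resp[[sprintf("cm_%02d", i)]] <- c(TRUE, FALSE)
  for (i in 1:18) resp[[sprintf("tfeq_%02d", i)]] <- c(4L, 1L)
  meals <- data.frame(participant_id = c(1, 1, 2), at_home = c(TRUE, FALSE, TRUE),
                      instrument = "4DFR")
  sc <- score_responses(resp, meals)
  expect_equal(names(sc), c("participant_id", dietcalib:::.factors))
  expect_equal(sc$socdes, c(33, 0))
  expect_equal(sc$unc, c(36, 9))
  expect_equal(sc$body, c(1, 0))
  expect_equal(sc$meals, c(50, 100))
})
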