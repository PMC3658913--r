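# Scoring of the raw psychosocial instruments and the meals-at-home behavior,
# plus low/medium/high categorization.

#' Score the Crowne-Marlowe social desirability scale
#'
#' The scale has 33 true/false items; the score is the number of items
#' answered in the keyed (socially desirable) direction, so higher scores
#' indicate greater social desirability. The published classification bands
#' are high 20--33, medium 9--19, low < 9.
#'
#' @param items Logical (or 0/1) vector of 33 responses, `TRUE` = "true".
#' @param key Logical vector of 33 keyed directions: the response that counts
#'   as socially desirable for each item. Default keys every item `TRUE`.
#' @return A list with `score` (0--33) and `class`
#'   (`"low"`/`"medium"`/`"high"` per the published bands).
#' @export
#' @examples
#' score_social_desirability(rep(TRUE, 33))$score  # 33
score_social_desirability <- function(items, key = rep(TRUE, 33)) {
  if (length(items) != 33 || anyNA(items))
    stop("exactly 33 non-missing true/false items are required",
         call. = FALSE)
  if (length(key) != 33)
    stop("key must have 33 elements", call. = FALSE)
  score <- sum(as.logical(items) == as.logical(key))
  class <- if (score >= 20) "high" else if (score >= 9) "medium" else "low"
  list(score = score, class = class)
}

#' Default TFEQ-R18 item-to-scale mapping
#'
#' The 18-item Three Factor Eating Questionnaire assigns 6 items to cognitive
#' restraint, 9 to uncontrolled eating and 3 to emotional eating. This is the
#' instrument's standard assignment, exposed so alternative mappings can be
#' supplied to [score_tfeq()].
#'
#' @return A character vector of length 18 with values `"restraint"`,
#'   `"unc"`, `"emo"`.
#' @export
tfeq_default_mapping <- function() {
  m <- rep("unc", 18)
  m[c(2, 11, 12, 15, 16, 18)] <- "restraint"
  m[c(3, 6, 10)] <- "emo"
  m
}

#' Score the TFEQ-R18 eating scales
#'
#' Each of the 18 items is scored 1--4 and item scores are summed into the
#' three scale scores; a k-item scale therefore ranges over `[k, 4k]`.
#'
#' @param items Integer vector of 18 responses, each in 1..4.
#' @param mapping Character vector of length 18 assigning each item to one of
#'   `"restraint"`, `"unc"`, `"emo"`; default [tfeq_default_mapping()].
#' @return Named numeric vector with elements `restraint`, `unc`, `emo`.
#' @export
#' @examples
#' score_tfeq(rep(1L, 18))  # minima: 6, 9, 3
score_tfeq <- function(items, mapping = tfeq_default_mapping()) {
  if (length(items) != 18 || anyNA(items))
    stop("exactly 18 non-missing items are required", call. = FALSE)
  if (any(items < 1 | items > 4 | items != round(items)))
    stop("item responses must be integers in 1..4", call. = FALSE)
  if (length(mapping) != 18 ||
      !all(mapping %in% c("restraint", "unc", "emo")))
    stop("mapping must assign each of 18 items to one scale", call. = FALSE)
  vapply(c("restraint", "unc", "emo"),
         function(s) sum(items[mapping == s]), numeric(1))
}

#' Body-image discordance from silhouette choices
#'
#' Discordance is the perceived current body silhouette minus the silhouette
#' perceived as the healthy ideal for oneself, on the 9-figure scale (signed;
#' positive values mean perceiving oneself larger than one's ideal).
#'
#' @param perceived,ideal_self Integers in 1..9.
#' @return Integer discordance `perceived - ideal_self`.
#' @export
#' @examples
#' body_image_discordance(5, 4)  # 1
body_image_discordance <- function(perceived, ideal_self) {
  ok <- function(x) all(is.na(x) | (x >= 1 & x <= 9 & x == round(x)))
  if (!ok(perceived) || !ok(ideal_self))
    stop("silhouette values must be integers in 1..9", call. = FALSE)
  perceived - ideal_self
}

#' Percent of meals eaten at home
#'
#' Computes `100 * (#meals at home) / (#meals)` over the meal records of one
#' instrument. Meal-location data come from the food record and the dietary
#' recall only; analyses use the four-day food record by default because it
#' covers more days.
#'
#' @param records A data.frame of meal records with at least columns
#'   `participant_id`, `at_home` (logical) and `instrument`.
#' @param instrument Which instrument's records to use (default `"4DFR"`).
#' @return A data.frame with `participant_id` and `pct_meals_home`;
#'   participants with no meals on the chosen instrument get `NA`.
#' @export
percent_meals_home <- function(records, instrument = "4DFR") {
  stopifnot(all(c("participant_id", "at_home", "instrument") %in%
                  names(records)))
  rec <- records[records$instrument == instrument, , drop = FALSE]
  ids <- unique(records$participant_id)
  if (!nrow(rec))
    return(data.frame(participant_id = ids, pct_meals_home = NA_real_))
  agg <- stats::aggregate(at_home ~ participant_id, data = rec,
                          FUN = function(x) 100 * mean(as.logical(x)))
  names(agg)[2] <- "pct_meals_home"
  out <- merge(data.frame(participant_id = ids), agg,
               by = "participant_id", all.x = TRUE)
  out[order(out$participant_id), , drop = FALSE]
}

#' Categorize scores into low/medium/high
#'
#' Applies a `(low_max, med_max)` threshold pair: low if
#' `score <= low_max`, medium if `low_max < score <= med_max`, high
#' otherwise — intervals closed on the right of each lower category,
#' matching the study's printed "<=" convention. Missing scores stay missing.
#'
#' @param scores Numeric vector.
#' @param cutoffs Numeric `c(low_max, med_max)` with `low_max < med_max`,
#'   e.g. one element of [printed_cutoffs()] or of
#'   [compute_tertile_cutoffs()].
#' @return A factor with levels `L`, `M`, `H`.
#' @export
#' @examples
#' categorize(c(19, 20, 24, 25), printed_cutoffs()$socdes)  # L M M H
categorize <- function(scores, cutoffs) {
  if (length(cutoffs) != 2 || !(cutoffs[1] < cutoffs[2]))
    stop("cutoffs must be an ordered pair (low_max, med_max)", call. = FALSE)
  lab <- ifelse(scores <= cutoffs[1], "L",
                ifelse(scores <= cutoffs[2], "M", "H"))
  factor(lab, levels = c("L", "M", "H"))
}

#' Empirical tertile cut-offs
#'
#' Computes `(low_max, med_max)` at the empirical 1/3 and 2/3 quantiles of
#' the non-missing scores, using the inverse-empirical-CDF quantile
#' (`type = 1`) so that cut-offs are observed score values.
#'
#' @param scores Numeric vector with at least 3 distinct non-missing values.
#' @return Numeric `c(low_max, med_max)`.
#' @export
#' @examples
#' compute_tertile_cutoffs(1:9)  # 3, 6
compute_tertile_cutoffs <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct values to form tertiles", call. = FALSE)
  q <- stats::quantile(x, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  if (!(q[1] < q[2]))
    stop("degenerate tertiles: 1/3 and 2/3 quantiles coincide",
         call. = FALSE)
  c(low_max = q[1], med_max = q[2])
}

#' Score a raw-response table
#'
#' Convenience wrapper turning a participant-per-row raw response table
#' (Crowne-Marlowe items `cm_01..cm_33`, TFEQ items `tfeq_01..tfeq_18`,
#' silhouette columns `perceived` and `ideal_self`) plus a meal-record table
#' into the six-factor score table used downstream.
#'
#' @param responses Data.frame of raw responses, one row per participant.
#' @param meals Data.frame of meal records for [percent_meals_home()].
#' @param cm_key Keyed directions for the Crowne-Marlowe items.
#' @param tfeq_mapping Item-to-scale mapping for the TFEQ items.
#' @return A data.frame with `participant_id` and the six factor scores
#'   (`meals`, `body`, `restraint`, `unc`, `emo`, `socdes`).
#' @export
score_responses <- function(responses, meals,
                            cm_key = rep(TRUE, 33),
                            tfeq_mapping = tfeq_default_mapping()) {
  cm_cols <- sprintf("cm_%02d", 1:33)
  tf_cols <- sprintf("tfeq_%02d", 1:18)
  stopifnot(all(c("participant_id", "perceived", "ideal_self") %in%
                  names(responses)),
            all(cm_cols %in% names(responses)),
            all(tf_cols %in% names(responses)))
  n <- nrow(responses)
  socdes <- numeric(n)
  tfeq <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("restraint", "unc", "emo")))
  for (i in seq_len(n)) {
    socdes[i] <- score_social_desirability(
      unlist(responses[i, cm_cols]), cm_key)$score
    tfeq[i, ] <- score_tfeq(as.integer(unlist(responses[i, tf_cols])),
                            tfeq_mapping)
  }
  body <- body_image_discordance(responses$perceived, responses$ideal_self)
  pm <- percent_meals_home(meals)
  out <- data.frame(participant_id = responses$participant_id,
                    body = body, restraint = tfeq[, "restraint"],
                    unc = tfeq[, "unc"], emo = tfeq[, "emo"],
                    socdes = socdes)
  out <- merge(pm, out, by = "participant_id", all.y = TRUE)
  names(out)[names(out) == "pct_meals_home"] <- "meals"
  out[, c("participant_id", .factors)]
}
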