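# Synthetic cohort generator: participants, psychosocial scores, latent
# intake, biomarkers with a reliability replicate, and self-reports under the
# measurement models
#   W = Z + e                       (classical biomarker model)
#   Q = S0 + S1 Z + S2 V + r + u    (self-report model; interactions optional)

.maybe_seed <- function(config, stage) {
  if (!is.null(config$seed)) set.seed(stage_seed(config$seed, stage))
  invisible(NULL)
}

.sample_bands <- function(n, bands) {
  band <- sample.int(nrow(bands), n, replace = TRUE, prob = bands[, "weight"])
  stats::runif(n, bands[band, "lo"], bands[band, "hi"])
}

#' Generate the participant table
#'
#' Draws demographics (age, BMI, race/ethnicity) from the configured strata
#' weights and flags `floor(n * reliability_fraction)` participants as the
#' reliability subsample that repeats the biomarker protocol.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `participant_id`, `age`, `bmi`, `race`
#'   and logical `reliability`.
#' @export
#' @examples
#' p <- generate_participants(cohort_config(n = 50, seed = 1))
#' sum(p$reliability)
generate_participants <- function(config) {
  validate_config(config)
  .maybe_seed(config, "participants")
  n <- config$n
  race <- sample(names(config$race_weights), n, replace = TRUE,
                 prob = config$race_weights)
  age <- .sample_bands(n, config$age_bands)
  bmi <- .sample_bands(n, config$bmi_bands)
  k <- floor(n * config$reliability_fraction)
  reliability <- logical(n)
  reliability[sample.int(n, k)] <- TRUE
  data.frame(participant_id = seq_len(n), age = age, bmi = bmi,
             race = factor(race, levels = .races),
             reliability = reliability)
}

#' Generate psychosocial and diet-behavior scores
#'
#' Draws the six factor scores (percent of meals at home, body-image
#' discordance, cognitive restraint, uncontrolled eating, emotional eating,
#' social desirability) from a latent Gaussian correlated across factors and
#' with standardized BMI, then maps each latent to the instrument's bounded
#' (and, except for meals, integer) support by scaling, rounding and
#' clipping. Defaults reproduce the configured means/SDs and the sign pattern
#' of the configured correlations.
#'
#' @param participants Output of [generate_participants()].
#' @param config A [cohort_config()].
#' @return A data.frame with `participant_id` and one column per factor.
#' @export
generate_psychosocial <- function(participants, config) {
  validate_config(config)
  .maybe_seed(config, "psychosocial")
  n <- nrow(participants)
  b <- config$bmi_corr[.factors]
  C <- config$psych_corr[.factors, .factors]
  # conditional covariance of the factor latents given standardized BMI
  Sc <- C - tcrossprod(b)
  ev <- eigen(Sc, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  L <- ev$vectors %*% diag(sqrt(ev$values), length(ev$values))
  bstd <- if (n > 1 && stats::sd(participants$bmi) > 0)
    as.numeric(scale(participants$bmi)) else rep(0, n)
  z <- matrix(stats::rnorm(n * 6), n, 6)
  latent <- outer(bstd, b) + z %*% t(L)
  out <- data.frame(participant_id = participants$participant_id)
  for (j in seq_along(.factors)) {
    f <- .factors[j]
    x <- config$psych_means[f] + config$psych_sds[f] * latent[, j]
    if (.factor_integer[f]) x <- round(x)
    s <- .factor_support[[f]]
    out[[f]] <- pmin(pmax(x, s[1]), s[2])
  }
  out
}

#' Generate latent log intake
#'
#' Draws latent log energy (kcal/d) and log protein (g/d) intake from a
#' bivariate normal whose means depend linearly on BMI and age (centered at
#' their sample means). Rows violating the physiological constraint that
#' protein energy (4 kcal/g) be below total energy are redrawn.
#'
#' @inheritParams generate_psychosocial
#' @return A data.frame with `participant_id`, `z_energy`, `z_protein`
#'   (log scale).
#' @export
generate_latent_intake <- function(participants, config) {
  validate_config(config)
  .maybe_seed(config, "latent_intake")
  n <- nrow(participants)
  bmi_c <- participants$bmi - mean(participants$bmi)
  age_c <- participants$age - mean(participants$age)
  mu_e <- config$z_mean["energy"] + config$z_bmi_coef["energy"] * bmi_c +
    config$z_age_coef["energy"] * age_c
  mu_p <- config$z_mean["protein"] + config$z_bmi_coef["protein"] * bmi_c +
    config$z_age_coef["protein"] * age_c
  s <- config$z_resid_sd
  r <- config$z_corr
  draw <- function(m) {
    z1 <- stats::rnorm(m)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(m)
    cbind(s["energy"] * z1, s["protein"] * z2)
  }
  res <- draw(n)
  ze <- mu_e + res[, 1]
  zp <- mu_p + res[, 2]
  # enforce 4 * exp(z_protein) < exp(z_energy) by rejection
  for (iter in seq_len(1000)) {
    bad <- which(zp + log(.kcal_per_g_protein) >= ze)
    if (!length(bad)) break
    res <- draw(length(bad))
    ze[bad] <- mu_e[bad] + res[, 1]
    zp[bad] <- mu_p[bad] + res[, 2]
  }
  if (length(bad <- which(zp + log(.kcal_per_g_protein) >= ze)))
    stop("could not satisfy protein-energy consistency after 1000 redraws")
  data.frame(participant_id = participants$participant_id,
             z_energy = ze, z_protein = zp)
}

#' Generate biomarker measurements
#'
#' Applies the classical measurement model: the primary log biomarker is
#' `W1 = Z + e1` for every participant, and the reliability subsample
#' additionally receives `W2 = Z + e2` with `corr(e1, e2) = rho`.
#'
#' @param latent Output of [generate_latent_intake()].
#' @param participants Output of [generate_participants()] (supplies the
#'   reliability flags).
#' @inheritParams generate_psychosocial
#' @return A long data.frame: `participant_id`, `nutrient`
#'   (`energy`/`protein`), `logw1`, `logw2` (`NA` outside the reliability
#'   subsample).
#' @export
generate_biomarkers <- function(latent, participants, config) {
  validate_config(config)
  .maybe_seed(config, "biomarkers")
  rho <- config$rho
  out <- lapply(c("energy", "protein"), function(nu) {
    z <- latent[[c(energy = "z_energy", protein = "z_protein")[nu]]]
    sd_e <- config$sd_e[nu]
    n <- length(z)
    e1 <- stats::rnorm(n, 0, sd_e)
    w2 <- rep(NA_real_, n)
    fl <- which(participants$reliability)
    if (length(fl)) {
      e2 <- rho * e1[fl] + sqrt(max(0, 1 - rho^2)) *
        stats::rnorm(length(fl), 0, sd_e)
      w2[fl] <- z[fl] + e2
    }
    data.frame(participant_id = latent$participant_id, nutrient = nu,
               logw1 = z + e1, logw2 = w2)
  })
  do.call(rbind, out)
}

# Covariate design V used both in self-report generation and in the fitted
# models: centered BMI and age, race dummies (reference Non-Hispanic White,
# Asian/Pacific Islander merged into Other), and M/H dummies for each factor.
.v_design <- function(participants, psych, cutoffs = printed_cutoffs(),
                      center = TRUE) {
  n <- nrow(participants)
  V <- matrix(0, n, length(.v_columns),
              dimnames = list(NULL, .v_columns))
  V[, "bmi"] <- if (center) participants$bmi - mean(participants$bmi) else
    participants$bmi
  V[, "age"] <- if (center) participants$age - mean(participants$age) else
    participants$age
  race <- as.character(participants$race)
  V[, "race_black"] <- as.numeric(race == "Black")
  V[, "race_hispanic"] <- as.numeric(race == "Hispanic")
  V[, "race_other"] <- as.numeric(race %in%
                                    c("Asian/Pacific Islander", "Other"))
  for (f in .factors) {
    cat3 <- categorize(psych[[f]], cutoffs[[f]])
    V[, paste0(f, "_M")] <- as.numeric(cat3 == "M")
    V[, paste0(f, "_H")] <- as.numeric(cat3 == "H")
  }
  V
}

#' Generate self-reported intakes
#'
#' Applies the flexible self-report measurement model per instrument and
#' nutrient: on the log scale,
#' `Q = mu_Z + bias0 + slope (Z - mu_Z) + coefs' V + r + u`, where `V` is the
#' covariate design built from the participants' characteristics and
#' categorized psychosocial scores (fixed cut-offs), `r` is a person-specific
#' reporting error (optionally shared across instruments within participant
#' and nutrient) and `u` an occasion error.
#'
#' @param latent Output of [generate_latent_intake()].
#' @param participants Output of [generate_participants()].
#' @param psych Output of [generate_psychosocial()].
#' @inheritParams generate_psychosocial
#' @return A long data.frame: `participant_id`, `instrument`
#'   (`ffq`/`dfr4`/`hr24`), `nutrient` (`energy`/`protein`), `logq`.
#' @export
generate_self_reports <- function(latent, participants, psych, config) {
  validate_config(config)
  .maybe_seed(config, "self_reports")
  n <- nrow(participants)
  V <- .v_design(participants, psych)
  zcols <- c(energy = "z_energy", protein = "z_protein")
  # person-specific standard-normal error, shared across instruments when
  # configured (scaled by each instrument's var_r)
  r0 <- list(energy = stats::rnorm(n), protein = stats::rnorm(n))
  rows <- list()
  for (ins in .instruments) {
    for (nu in names(config$selfreport[[ins]])) {
      p <- config$selfreport[[ins]][[nu]]
      beta <- stats::setNames(numeric(length(.v_columns)), .v_columns)
      beta[names(p$coefs)] <- p$coefs
      mu <- config$z_mean[nu]
      r <- if (config$share_person_error) sqrt(p$var_r) * r0[[nu]] else
        stats::rnorm(n, 0, sqrt(p$var_r))
      u <- stats::rnorm(n, 0, sqrt(p$var_u))
      q <- mu + p$bias0 + p$slope * (latent[[zcols[nu]]] - mu) +
        drop(V %*% beta) + r + u
      rows[[paste(ins, nu)]] <-
        data.frame(participant_id = participants$participant_id,
                   instrument = ins, nutrient = nu, logq = q)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete cohort
#'
#' Runs every generation stage (participants, psychosocial scores, latent
#' intake, biomarkers, self-reports) under per-stage seeds derived from the
#' master seed, so identical configurations reproduce byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return An object of class `dietcal_cohort`: a list with elements
#'   `participants`, `psychosocial`, `intake_truth`, `biomarkers`,
#'   `selfreports` and the `config` used.
#' @seealso [write_cohort()], [build_analysis_table()]
#' @export
#' @examples
#' ch <- simulate_cohort(cohort_config(n = 80, seed = 7))
#' nrow(ch$participants)
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  participants <- generate_participants(config)
  psych <- generate_psychosocial(participants, config)
  latent <- generate_latent_intake(participants, config)
  biomarkers <- generate_biomarkers(latent, participants, config)
  selfreports <- generate_self_reports(latent, participants, psych, config)
  structure(list(participants = participants, psychosocial = psych,
                 intake_truth = latent, biomarkers = biomarkers,
                 selfreports = selfreports, config = config),
            class = "dietcal_cohort")
}

#' @export
print.dietcal_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d with reliability replicate)\n",
              nrow(x$participants), sum(x$participants$reliability)))
  cat(sprintf("  self-reports: %d rows (%s x %s)\n", nrow(x$selfreports),
              paste(.instrument_labels[.instruments], collapse = "/"),
              "energy/protein"))
  invisible(x)
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `participants.csv`, `psychosocial.csv`,
#' `intake_truth.csv`, `biomarkers.csv` and `selfreports.csv` into a
#' directory; intake values are written on the raw scale (kcal/d, g/d),
#' latent truth on the log scale. `read_cohort()` reads them back into a
#' `dietcal_cohort` (without a config).
#'
#' @param cohort A `dietcal_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` a `dietcal_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dietcal_cohort") || is.list(cohort))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bm <- cohort$biomarkers
  bm_out <- data.frame(participant_id = bm$participant_id,
                       nutrient = bm$nutrient,
                       primary = exp(bm$logw1),
                       replicate = exp(bm$logw2))
  sr <- cohort$selfreports
  sr_out <- data.frame(participant_id = sr$participant_id,
                       instrument = .instrument_labels[sr$instrument],
                       nutrient = sr$nutrient,
                       value = exp(sr$logq))
  paths <- c(participants = file.path(dir, "participants.csv"),
             psychosocial = file.path(dir, "psychosocial.csv"),
             intake_truth = file.path(dir, "intake_truth.csv"),
             biomarkers = file.path(dir, "biomarkers.csv"),
             selfreports = file.path(dir, "selfreports.csv"))
  utils::write.csv(cohort$participants, paths["participants"],
                   row.names = FALSE)
  utils::write.csv(cohort$psychosocial, paths["psychosocial"],
                   row.names = FALSE)
  utils::write.csv(cohort$intake_truth, paths["intake_truth"],
                   row.names = FALSE)
  utils::write.csv(bm_out, paths["biomarkers"], row.names = FALSE)
  utils::write.csv(sr_out, paths["selfreports"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  participants <- rd("participants.csv")
  participants$race <- factor(participants$race, levels = .races)
  bm <- rd("biomarkers.csv")
  biomarkers <- data.frame(participant_id = bm$participant_id,
                           nutrient = bm$nutrient,
                           logw1 = log(bm$primary),
                           logw2 = log(bm$replicate))
  sr <- rd("selfreports.csv")
  code <- stats::setNames(names(.instrument_labels), .instrument_labels)
  selfreports <- data.frame(participant_id = sr$participant_id,
                            instrument = code[sr$instrument],
                            nutrient = sr$nutrient,
                            logq = log(sr$value))
  rownames(selfreports) <- NULL
  structure(list(participants = participants,
                 psychosocial = rd("psychosocial.csv"),
                 intake_truth = rd("intake_truth.csv"),
                 biomarkers = biomarkers, selfreports = selfreports,
                 config = NULL),
            class = "dietcal_cohort")
}
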