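# Shared constants: factor codes, instrument codes, nutrient codes, cut-offs.

# Six psychosocial / diet-behavior factors, in the fixed order used by every
# design matrix and output table.
.factors <- c("meals", "body", "restraint", "unc", "emo", "socdes")

.factor_labels <- c(
  meals     = "Meals at home (%)",
  body      = "Body image discordance",
  restraint = "Cognitive restraint",
  unc       = "Uncontrolled eating",
  emo       = "Emotional eating",
  socdes    = "Social desirability"
)

# Bounded supports of each score. meals is continuous percent; the others are
# integer-valued instrument scales.
.factor_support <- list(
  meals     = c(0, 100),
  body      = c(-8, 8),
  restraint = c(6, 24),
  unc       = c(9, 36),
  emo       = c(3, 12),
  socdes    = c(0, 33)
)

.factor_integer <- c(meals = FALSE, body = TRUE, restraint = TRUE,
                     unc = TRUE, emo = TRUE, socdes = TRUE)

.instruments <- c("ffq", "dfr4", "hr24")
.instrument_labels <- c(ffq = "FFQ", dfr4 = "4DFR", hr24 = "24HR")

.nutrients <- c("energy", "protein", "pdens")
.nutrient_labels <- c(energy = "Energy", protein = "Protein",
                      pdens = "Protein density")

.races <- c("Non-Hispanic White", "Black", "Hispanic",
            "Asian/Pacific Islander", "Other")

# Covariate design column names (excluding intercept and self-report columns);
# the order is the fixed group order of the analysis tables.
.v_columns <- c("bmi", "age", "race_black", "race_hispanic", "race_other",
                paste0(rep(.factors, each = 2), "_", c("M", "H")))

# kcal per gram of protein (Atwater factor); config constant.
.kcal_per_g_protein <- 4

#' Fixed low/medium/high cut-offs for the six factors
#'
#' Returns the study's fixed categorization thresholds: each factor is cut
#' into low (score <= low_max), medium (low_max < score <= med_max) and high
#' (score > med_max). Body-image discordance uses the <1 / 1--2 / >=3 scheme,
#' which for integer discordances is `(0, 2)`; the remaining factors use
#' tertile-derived thresholds fixed by the study.
#'
#' @return A named list with one `c(low_max, med_max)` pair per factor
#'   (`meals`, `body`, `restraint`, `unc`, `emo`, `socdes`).
#' @seealso [categorize()], [compute_tertile_cutoffs()]
#' @export
#' @examples
#' printed_cutoffs()$socdes  # c(19, 24)
printed_cutoffs <- function() {
  list(
    meals     = c(low_max = 79.6, med_max = 92.3),
    body      = c(low_max = 0,    med_max = 2),
    restraint = c(low_max = 14,   med_max = 16),
    unc       = c(low_max = 24,   med_max = 27),
    emo       = c(low_max = 7,    med_max = 10),
    socdes    = c(low_max = 19,   med_max = 24)
  )
}

# Default 6x6 correlation matrix over the factor latents, from the study's
# reported pairwise correlations (unreported pairs set to 0), plus the
# correlation of each factor latent with standardized BMI.
.default_psych_corr <- function() {
  C <- diag(6)
  dimnames(C) <- list(.factors, .factors)
  set <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set("restraint", "unc", 0.15)
  set("restraint", "emo", 0.14)
  set("unc", "emo", 0.60)
  set("socdes", "unc", 0.25)
  set("socdes", "emo", 0.29)
  set("body", "restraint", -0.35)
  set("body", "emo", -0.38)
  set("meals", "unc", 0.096)
  C
}

.default_bmi_corr <- c(meals = 0, body = 0, restraint = 0.06,
                       unc = -0.27, emo = -0.40, socdes = 0)

.default_selfreport <- function() {
  sr <- list(
    ffq = list(
      energy = list(bias0 = -0.20, slope = 0.50,
                    coefs = c(socdes_H = -0.174, meals_H = 0.181,
                              race_black = -0.253, race_hispanic = -0.179,
                              age = 0.0072),
                    var_r = 0.040, var_u = 0.020),
      protein = list(bias0 = -0.15, slope = 0.45,
                     coefs = c(socdes_H = -0.142, meals_H = 0.127,
                               race_black = -0.199, age = 0.0087),
                     var_r = 0.060, var_u = 0.030)
    ),
    dfr4 = list(
      energy = list(bias0 = -0.05, slope = 0.75,
                    coefs = c(bmi = -0.0113, age = 0.0064),
                    var_r = 0.012, var_u = 0.012),
      protein = list(bias0 = -0.03, slope = 0.80,
                     coefs = c(race_black = 0.094, bmi = -0.0064,
                               age = 0.0074),
                     var_r = 0.020, var_u = 0.020)
    ),
    hr24 = list(
      energy = list(bias0 = -0.08, slope = 0.65,
                    coefs = c(bmi = -0.016, age = 0.0062),
                    var_r = 0.015, var_u = 0.020),
      protein = list(bias0 = -0.10, slope = 0.70,
                     coefs = c(race_black = 0.116, bmi = -0.0099,
                               age = 0.0104),
                     var_r = 0.025, var_u = 0.030)
    )
  )
  sr
}

#' Cohort simulation configuration
#'
#' Builds the configuration object consumed by [simulate_cohort()] and
#' [run_pipeline()]. The defaults encode the study conditions the package
#' emulates: 450 postmenopausal women with Black, Hispanic, younger, and
#' high/low-BMI strata oversampled; a 19.6% reliability subsample repeating
#' the biomarker protocol; psychosocial score distributions matching the
#' reported means, SDs and inter-correlations; log-normal latent intake with
#' configurable BMI and age dependence; classical biomarker error; and a
#' flexible self-report measurement model with covariate-driven bias.
#'
#' @param n Number of participants (default 450).
#' @param reliability_fraction Fraction of participants repeating the
#'   biomarker protocol (default 0.196, i.e. 88 of 450).
#' @param race_weights Named sampling proportions over the five race/ethnicity
#'   groups; must sum to 1.
#' @param age_bands,bmi_bands Three-column matrices (`lo`, `hi`, `weight`):
#'   band limits and sampling weights; weights must sum to 1. Values are drawn
#'   uniformly within the sampled band.
#' @param psych_means,psych_sds Named per-factor means and SDs of the six
#'   psychosocial/diet-behavior scores.
#' @param psych_corr 6x6 correlation matrix over the factor latents (must be
#'   positive semi-definite together with `bmi_corr`).
#' @param bmi_corr Named length-6 vector: correlation of each factor latent
#'   with standardized BMI.
#' @param z_mean Named log-scale means of latent energy (log kcal/d) and
#'   protein (log g/d) intake.
#' @param z_bmi_coef,z_age_coef Linear dependence of the latent log intakes on
#'   BMI (per kg/m^2) and age (per year), both centered at their sample means.
#' @param z_resid_sd Residual SDs of the latent log intakes.
#' @param z_corr Residual correlation between latent log energy and protein.
#' @param sd_e Named biomarker error SDs on the log scale.
#' @param rho Correlation between the primary and reliability biomarker
#'   errors used in generation (default 0); must lie in (-1, 1).
#' @param selfreport Nested list `instrument -> nutrient -> parameters`
#'   (`bias0`, `slope`, `coefs`, `var_r`, `var_u`) of the self-report
#'   measurement model; see Details.
#' @param share_person_error Logical; if `TRUE` (default) the person-specific
#'   reporting error is drawn once per participant and nutrient and shared
#'   (scaled by each instrument's `var_r`) across instruments.
#' @param n_bootstrap Bootstrap replicates used by [run_pipeline()]
#'   (default 5000).
#' @param rho_grid Replicate-error correlations for the adjusted-R2
#'   sensitivity analysis (default `c(0, -0.1, -0.2)`).
#' @param seed Master seed; per-stage seeds are derived from it by stage name.
#'
#' @details Self-report intakes follow, on the log scale,
#' `Q = mu_Z + bias0 + slope * (Z - mu_Z) + coefs %*% V + r + u`, where `V`
#' is the covariate design (centered BMI and age, race dummies, and M/H
#' category dummies of the six factors under the fixed cut-offs), `r` is a
#' person-specific error with variance `var_r` and `u` an occasion error with
#' variance `var_u`. `coefs` is a sparse named vector over
#' `dietcalib:::.v_columns`.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [read_config()], [run_pipeline()]
#' @export
#' @examples
#' cfg <- cohort_config(n = 100, seed = 1)
#' cfg$reliability_fraction
cohort_config <- function(n = 450,
                          reliability_fraction = 0.196,
                          race_weights = c("Non-Hispanic White" = 0.640,
                                           "Black" = 0.187,
                                           "Hispanic" = 0.142,
                                           "Asian/Pacific Islander" = 0.018,
                                           "Other" = 0.013),
                          age_bands = cbind(lo = c(59, 69, 79),
                                            hi = c(69, 79, 91),
                                            weight = c(0.473, 0.422, 0.105)),
                          bmi_bands = cbind(lo = c(19, 25, 30),
                                            hi = c(25, 30, 45),
                                            weight = c(0.347, 0.269, 0.384)),
                          psych_means = c(meals = 83.0, body = 1.25,
                                          restraint = 15.24, unc = 25.66,
                                          emo = 8.47, socdes = 21.07),
                          psych_sds = c(meals = 13.0, body = 1.06,
                                        restraint = 1.98, unc = 3.47,
                                        emo = 2.6, socdes = 5.35),
                          psych_corr = .default_psych_corr(),
                          bmi_corr = .default_bmi_corr,
                          z_mean = c(energy = 7.601, protein = 4.248),
                          z_bmi_coef = c(energy = 0.015, protein = 0.008),
                          z_age_coef = c(energy = -0.009, protein = -0.010),
                          z_resid_sd = c(energy = 0.134, protein = 0.212),
                          z_corr = 0.7,
                          sd_e = c(energy = 0.13, protein = 0.25),
                          rho = 0,
                          selfreport = .default_selfreport(),
                          share_person_error = TRUE,
                          n_bootstrap = 5000,
                          rho_grid = c(0, -0.1, -0.2),
                          seed = NULL) {
  cfg <- list(n = as.integer(n),
              reliability_fraction = reliability_fraction,
              race_weights = race_weights,
              age_bands = age_bands, bmi_bands = bmi_bands,
              psych_means = psych_means, psych_sds = psych_sds,
              psych_corr = psych_corr, bmi_corr = bmi_corr,
              z_mean = z_mean, z_bmi_coef = z_bmi_coef,
              z_age_coef = z_age_coef, z_resid_sd = z_resid_sd,
              z_corr = z_corr, sd_e = sd_e, rho = rho,
              selfreport = selfreport,
              share_person_error = isTRUE(share_person_error),
              n_bootstrap = as.integer(n_bootstrap),
              rho_grid = rho_grid,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.finite(cfg$n) || cfg$n < 1)
    stop("n must be a positive integer", call. = FALSE)
  if (cfg$reliability_fraction < 0 || cfg$reliability_fraction > 1)
    stop("reliability_fraction must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$race_weights) - 1) > 1e-9)
    stop("race_weights must sum to 1", call. = FALSE)
  if (!setequal(names(cfg$race_weights), .races))
    stop("race_weights must be named over the five race/ethnicity groups",
         call. = FALSE)
  for (b in c("age_bands", "bmi_bands")) {
    m <- cfg[[b]]
    if (abs(sum(m[, "weight"]) - 1) > 1e-9)
      stop(b, " weights must sum to 1", call. = FALSE)
    if (any(m[, "hi"] <= m[, "lo"]))
      stop(b, " must have hi > lo", call. = FALSE)
  }
  for (v in c("psych_means", "psych_sds"))
    if (!setequal(names(cfg[[v]]), .factors))
      stop(v, " must be named over the six factors", call. = FALSE)
  if (any(cfg$psych_sds < 0)) stop("psych_sds must be >= 0", call. = FALSE)
  C <- cfg$psych_corr
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("psych_corr must be symmetric", call. = FALSE)
  # joint latent (BMI + six factors) must be PSD
  J <- rbind(c(1, cfg$bmi_corr[.factors]),
             cbind(cfg$bmi_corr[.factors], C[.factors, .factors]))
  if (min(eigen(J, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("psych_corr with bmi_corr is not positive semi-definite",
         call. = FALSE)
  if (any(cfg$z_resid_sd < 0))
    stop("z_resid_sd must be >= 0", call. = FALSE)
  if (abs(cfg$z_corr) > 1) stop("z_corr must lie in [-1, 1]", call. = FALSE)
  if (any(cfg$sd_e < 0)) stop("sd_e must be >= 0", call. = FALSE)
  if (abs(cfg$rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  for (ins in names(cfg$selfreport)) {
    for (nu in names(cfg$selfreport[[ins]])) {
      p <- cfg$selfreport[[ins]][[nu]]
      if (p$var_r < 0 || p$var_u < 0)
        stop("var_r and var_u must be >= 0", call. = FALSE)
      bad <- setdiff(names(p$coefs), .v_columns)
      if (length(bad))
        stop("unknown self-report covariate coefficient(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort simulation configuration\n")
  cat(sprintf("  participants: %d (reliability subsample: %.1f%% = %d)\n",
              x$n, 100 * x$reliability_fraction,
              floor(x$n * x$reliability_fraction)))
  cat("  race weights:",
      paste(sprintf("%s %.1f%%", names(x$race_weights),
                    100 * x$race_weights), collapse = ", "), "\n")
  cat("  psychosocial means (SDs):\n")
  for (f in .factors)
    cat(sprintf("    %-24s %6.2f (%.2f)\n", .factor_labels[f],
                x$psych_means[f], x$psych_sds[f]))
  cat(sprintf("  latent log intake: energy %.3f (resid sd %.3f), protein %.3f (resid sd %.3f)\n",
              x$z_mean["energy"], x$z_resid_sd["energy"],
              x$z_mean["protein"], x$z_resid_sd["protein"]))
  cat(sprintf("  biomarker error sd: energy %.3f, protein %.3f; rho = %.2f\n",
              x$sd_e["energy"], x$sd_e["protein"], x$rho))
  cat(sprintf("  bootstrap replicates: %d; rho grid: %s\n",
              x$n_bootstrap, paste(x$rho_grid, collapse = ", ")))
  if (!is.null(x$seed)) cat(sprintf("  master seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' `read_config()` loads a YAML file and merges it over the defaults of
#' [cohort_config()]; `write_config()` serializes a configuration so a run
#' can be reproduced from file.
#'
#' @param file Path to a YAML file.
#' @param config A `cohort_config` object.
#' @return `read_config()` returns a `cohort_config`; `write_config()`
#'   returns `file` invisibly.
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  args <- list()
  simple <- c("n", "reliability_fraction", "z_corr", "rho",
              "share_person_error", "n_bootstrap", "rho_grid", "seed")
  named <- c("race_weights", "psych_means", "psych_sds", "bmi_corr",
             "z_mean", "z_bmi_coef", "z_age_coef", "z_resid_sd", "sd_e")
  for (k in intersect(simple, names(raw))) args[[k]] <- raw[[k]]
  for (k in intersect(named, names(raw))) args[[k]] <- unlist(raw[[k]])
  for (k in intersect(c("age_bands", "bmi_bands"), names(raw))) {
    m <- do.call(rbind, lapply(raw[[k]], unlist))
    args[[k]] <- m[, c("lo", "hi", "weight"), drop = FALSE]
  }
  if ("psych_corr" %in% names(raw)) {
    C <- do.call(rbind, lapply(raw$psych_corr, unlist))
    dimnames(C) <- list(.factors, .factors)
    args$psych_corr <- C
  }
  if ("selfreport" %in% names(raw)) {
    sr <- .default_selfreport()
    for (ins in names(raw$selfreport))
      for (nu in names(raw$selfreport[[ins]])) {
        p <- raw$selfreport[[ins]][[nu]]
        if (!is.null(p$coefs)) p$coefs <- unlist(p$coefs)
        sr[[ins]][[nu]] <- utils::modifyList(sr[[ins]][[nu]], p)
      }
    args$selfreport <- sr
  }
  do.call(cohort_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$age_bands <- apply(config$age_bands, 1, as.list, simplify = FALSE)
  x$bmi_bands <- apply(config$bmi_bands, 1, as.list, simplify = FALSE)
  x$psych_corr <- apply(config$psych_corr, 1, as.list, simplify = FALSE)
  for (nm in c("race_weights", "psych_means", "psych_sds", "bmi_corr",
               "z_mean", "z_bmi_coef", "z_age_coef", "z_resid_sd", "sd_e"))
    x[[nm]] <- as.list(config[[nm]])
  x$selfreport <- lapply(config$selfreport, function(ins)
    lapply(ins, function(p) {
      p$coefs <- as.list(p$coefs)
      p
    }))
  yaml::write_yaml(x, file)
  invisible(file)
}

# Deterministic per-stage seed derived from the master seed and a stage name,
# so stages can be rerun independently with identical output. Kept below 2^31.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 48271 + h * 8191) %% 2147483647)
}
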