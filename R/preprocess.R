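# Analysis-variable derivation: log intakes, protein density, outlier
# exclusion, centering, and the regression design shared by the bias and
# calibration fits.

#' Protein density: percent of energy from protein
#'
#' `100 * 4 * protein_g / energy_kcal`, using 4 kcal per gram of protein.
#'
#' @param energy_kcal Energy intake, kcal/d (> 0).
#' @param protein_g Protein intake, g/d (>= 0).
#' @return Percent of energy derived from protein.
#' @export
#' @examples
#' derive_protein_density(2000, 75)  # 15
derive_protein_density <- function(energy_kcal, protein_g) {
  if (any(energy_kcal <= 0, na.rm = TRUE))
    stop("energy must be positive", call. = FALSE)
  if (any(protein_g < 0, na.rm = TRUE))
    stop("protein must be non-negative", call. = FALSE)
  100 * .kcal_per_g_protein * protein_g / energy_kcal
}

#' Interquartile-range outlier mask
#'
#' A value is excluded when it lies outside the interquartile range by more
#' than three times its width: below `Q1 - 3 IQR` or above `Q3 + 3 IQR`.
#' Bounds are computed once from the non-missing values (single pass).
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return Logical inclusion mask (`TRUE` = keep; `NA` values stay `NA`),
#'   with the bounds attached as attribute `"bounds"`.
#' @export
#' @examples
#' mask <- flag_outliers(c(1:10, 100))
#' attr(mask, "bounds")
flag_outliers <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 4)
    stop("need at least 4 non-missing values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(lower = q[1] - 3 * iqr, upper = q[2] + 3 * iqr)
  keep <- values >= bounds["lower"] & values <= bounds["upper"]
  structure(keep, bounds = bounds)
}

#' Center a numeric vector at its mean
#'
#' @param values Numeric vector (`NA`s ignored for the mean).
#' @return The centered vector with the removed mean attached as attribute
#'   `"center"`, so intercepts can be back-transformed.
#' @export
center <- function(values) {
  m <- mean(values, na.rm = TRUE)
  structure(values - m, center = m)
}

#' Build the participant-level analysis table
#'
#' Joins the cohort tables into one row per participant, takes logs of all
#' intake measures, derives protein density from energy and protein (for the
#' biomarkers and each self-report instrument), applies the interquartile
#' outlier rule to every log-scale intake variable separately (excluded
#' values are set to `NA` and logged), and categorizes the six
#' psychosocial/diet-behavior factors.
#'
#' @param cohort A `dietcal_cohort` from [simulate_cohort()] or
#'   [read_cohort()], or a list with the same elements.
#' @param cutoffs `"printed"` (default) uses the study's fixed cut-offs for
#'   all factors; `"tertile"` recomputes empirical tertiles
#'   ([compute_tertile_cutoffs()]) for every factor except body-image
#'   discordance, which always uses the fixed <1 / 1--2 / >=3 scheme.
#' @param outlier_scale Scale on which the outlier rule is applied:
#'   `"log"` (default) or `"raw"`.
#' @return A data.frame with demographics, factor scores, `cat_*` category
#'   factors, `logw_*`/`logw2_*` biomarker columns and `logq_*_*`
#'   self-report columns (`NA` where excluded), with attributes
#'   `"exclusions"` (a log of excluded values with the bounds applied) and
#'   `"cutoffs"` (the scheme used).
#' @export
build_analysis_table <- function(cohort, cutoffs = c("printed", "tertile"),
                                 outlier_scale = c("log", "raw")) {
  cutoffs <- match.arg(cutoffs)
  outlier_scale <- match.arg(outlier_scale)
  at <- merge(cohort$participants, cohort$psychosocial,
              by = "participant_id")
  at <- at[order(at$participant_id), , drop = FALSE]

  # wide log biomarkers and self-reports
  bm <- cohort$biomarkers
  for (nu in c("energy", "protein")) {
    b <- bm[bm$nutrient == nu, ]
    at[[paste0("logw_", nu)]] <-
      b$logw1[match(at$participant_id, b$participant_id)]
    at[[paste0("logw2_", nu)]] <-
      b$logw2[match(at$participant_id, b$participant_id)]
  }
  # protein density on the log scale: log(100 * 4 * P / E)
  at$logw_pdens <- log(100 * .kcal_per_g_protein) +
    at$logw_protein - at$logw_energy
  at$logw2_pdens <- log(100 * .kcal_per_g_protein) +
    at$logw2_protein - at$logw2_energy
  sr <- cohort$selfreports
  for (ins in .instruments) {
    for (nu in c("energy", "protein")) {
      s <- sr[sr$instrument == ins & sr$nutrient == nu, ]
      at[[paste0("logq_", ins, "_", nu)]] <-
        s$logq[match(at$participant_id, s$participant_id)]
    }
    at[[paste0("logq_", ins, "_pdens")]] <-
      log(100 * .kcal_per_g_protein) +
      at[[paste0("logq_", ins, "_protein")]] -
      at[[paste0("logq_", ins, "_energy")]]
  }

  # outlier screening, per variable
  vars <- c(paste0("logw_", .nutrients), paste0("logw2_", .nutrients),
            as.vector(outer(.instruments, .nutrients,
                            function(i, n) paste0("logq_", i, "_", n))))
  excl <- list()
  for (v in vars) {
    x <- at[[v]]
    if (sum(!is.na(x)) < 4) next
    xs <- if (outlier_scale == "log") x else exp(x)
    keep <- flag_outliers(xs)
    bounds <- attr(keep, "bounds")
    out <- which(!is.na(keep) & !keep)
    if (length(out)) {
      excl[[v]] <- data.frame(participant_id = at$participant_id[out],
                              variable = v, value = xs[out],
                              lower = bounds["lower"],
                              upper = bounds["upper"],
                              row.names = NULL)
      at[[v]][out] <- NA
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE)) else
    data.frame(participant_id = integer(), variable = character(),
               value = numeric(), lower = numeric(), upper = numeric())

  # categorization
  scheme <- printed_cutoffs()
  if (cutoffs == "tertile")
    for (f in setdiff(.factors, "body"))
      scheme[[f]] <- compute_tertile_cutoffs(at[[f]])
  for (f in .factors)
    at[[paste0("cat_", f)]] <- categorize(at[[f]], scheme[[f]])

  structure(at, exclusions = exclusions, cutoffs = scheme)
}

# Assemble response, design matrix and predictor groups for one model.
# type = "calibration": y = log biomarker, design includes centered log
#   self-report column(s); type = "bias": y = log self-report minus log
#   biomarker for `bias_instrument`, design has no self-report columns.
.assemble_design <- function(data, nutrient,
                             instruments = .instruments,
                             psychosocial = TRUE,
                             type = c("calibration", "bias"),
                             bias_instrument = NULL) {
  type <- match.arg(type)
  stopifnot(nutrient %in% .nutrients)
  if (type == "calibration") {
    stopifnot(length(instruments) >= 1, all(instruments %in% .instruments))
    instruments <- .instruments[.instruments %in% instruments]
    qcols <- paste0("logq_", instruments, "_", nutrient)
  } else {
    stopifnot(bias_instrument %in% .instruments)
    qcols <- paste0("logq_", bias_instrument, "_", nutrient)
  }
  wcol <- paste0("logw_", nutrient)
  fac_cols <- if (psychosocial) paste0("cat_", .factors) else character()
  needed <- c(wcol, qcols, "bmi", "age", "race", fac_cols)
  ok <- stats::complete.cases(data[, needed, drop = FALSE])
  d <- data[ok, , drop = FALSE]
  if (!nrow(d)) stop("no complete cases for the requested model",
                     call. = FALSE)

  centers <- c()
  cols <- list()
  groups <- list()
  if (type == "calibration") {
    for (ins in instruments) {
      qc <- paste0("logq_", ins, "_", nutrient)
      cc <- center(d[[qc]])
      centers[qc] <- attr(cc, "center")
      nm <- paste0("log_", .instrument_labels[ins], "_c")
      cols[[nm]] <- as.numeric(cc)
      groups[[paste0("selfreport_", ins)]] <- nm
    }
  }
  for (v in c("bmi", "age")) {
    cc <- center(d[[v]])
    centers[v] <- attr(cc, "center")
    nm <- paste0(v, "_c")
    cols[[nm]] <- as.numeric(cc)
    groups[[v]] <- nm
  }
  race <- as.character(d$race)
  cols[["race_black"]] <- as.numeric(race == "Black")
  cols[["race_hispanic"]] <- as.numeric(race == "Hispanic")
  cols[["race_other"]] <- as.numeric(race %in%
                                       c("Asian/Pacific Islander", "Other"))
  groups[["race"]] <- c("race_black", "race_hispanic", "race_other")
  if (psychosocial) {
    for (f in .factors) {
      cat3 <- d[[paste0("cat_", f)]]
      mn <- paste0(f, "_M")
      hn <- paste0(f, "_H")
      cols[[mn]] <- as.numeric(cat3 == "M")
      cols[[hn]] <- as.numeric(cat3 == "H")
      groups[[f]] <- c(mn, hn)
    }
  }
  X <- cbind("(Intercept)" = 1, do.call(cbind, cols))
  y <- if (type == "calibration") d[[wcol]] else d[[qcols]] - d[[wcol]]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    const <- names(sds)[sds == 0]
    stop("design is rank-deficient",
         if (length(const)) paste0(" (constant column(s): ",
                                   paste(const, collapse = ", "), ")"),
         call. = FALSE)
  }
  list(X = X, y = y, qr = qrX, groups = groups, centers = centers,
       ids = d$participant_id, nutrient = nutrient,
       instruments = if (type == "calibration") instruments else
         bias_instrument)
}

#' Build a calibration design matrix
#'
#' Constructs the regression design used by the calibration equations:
#' intercept, centered log self-report intake per included instrument (in
#' FFQ, 4DFR, 24HR order), centered BMI and age, race dummies (reference
#' Non-Hispanic White, Asian/Pacific Islander merged into Other) and, if
#' requested, M/H indicator columns for each of the six categorized factors
#' (reference L). Rows are complete cases for all involved variables.
#'
#' @param data An analysis table from [build_analysis_table()].
#' @param nutrient One of `"energy"`, `"protein"`, `"pdens"`.
#' @param instruments Instruments whose (centered) log self-reports enter the
#'   design; subset of `c("ffq", "dfr4", "hr24")`.
#' @param psychosocial Include the six categorized factors (default `TRUE`).
#' @return A list: `X` (design matrix incl. intercept), `y` (log biomarker
#'   response), `groups` (named list mapping each predictor group to its
#'   columns, in the fixed order), `centers` (means removed from centered
#'   columns), `ids` (retained participant ids).
#' @export
build_design <- function(data, nutrient, instruments = .instruments,
                         psychosocial = TRUE) {
  des <- .assemble_design(data, nutrient, instruments, psychosocial,
                          type = "calibration")
  des[c("X", "y", "groups", "centers", "ids")]
}
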