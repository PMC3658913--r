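# Regression calibration core: OLS bias regressions (Q - W on covariates),
# calibration equations (W on Q + covariates), sequential R2 decomposition
# over predictor groups, and calibrated-intake prediction.
#
# Fits go through a single QR factorization; with the intercept first and the
# predictor groups in their fixed order, the squared elements of the QR
# effects vector are the sequential (type-I) sums of squares, so the group
# contributions telescope exactly to the total R2.

.ols_from_design <- function(des) {
  X <- des$X
  y <- des$y
  qrX <- des$qr
  n <- nrow(X)
  p <- ncol(X)
  coefs <- qr.coef(qrX, y)
  eff <- qr.qty(qrX, y)
  fitted <- drop(qr.fitted(qrX, y))
  resid <- y - fitted
  rss <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  # sequential SS per column (skip intercept), grouped
  col_ss <- eff[seq_len(p)]^2
  names(col_ss) <- colnames(X)
  # a constant response (e.g. an error-free reporter) has no variance to
  # decompose: report zero rather than 0/0
  r2_groups <- if (sst > 0)
    vapply(des$groups, function(cn) 100 * sum(col_ss[cn]) / sst, numeric(1))
  else vapply(des$groups, function(cn) 0, numeric(1))
  list(coefficients = coefs, se = se, tvalues = tval, pvalues = pval,
       fitted = fitted, residuals = resid, sigma = sqrt(sigma2),
       df_residual = df, n = n, rss = rss, sst = sst,
       r2_total = sum(r2_groups), r2_groups = r2_groups)
}

#' Fit a calibration equation
#'
#' Ordinary least squares of the log biomarker on the centered log
#' self-report intake(s) and participant characteristics: centered BMI and
#' age, race/ethnicity, and (by default) the six categorized psychosocial and
#' diet-behavior factors. Reports conventional OLS coefficients and standard
#' errors, and decomposes the total R2 sequentially over the predictor groups
#' in their fixed entry order (self-reports, BMI, age, race, meals at home,
#' body image, restraint, uncontrolled eating, emotional eating, social
#' desirability), so the per-group contributions sum exactly to the total.
#'
#' @param data An analysis table from [build_analysis_table()].
#' @param nutrient `"energy"`, `"protein"` or `"pdens"`.
#' @param instruments Which self-report instruments enter the equation
#'   (subset of `c("ffq", "dfr4", "hr24")`); default all three.
#' @param psychosocial Include the six categorized factors (default `TRUE`);
#'   `FALSE` gives the reduced equation used for nested comparisons.
#' @return An object of class `calibfit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#'   Components include `coefficients`, `se`, `pvalues`, `r2_groups`
#'   (percent), `r2_total` (percent), `centers` and `n`.
#' @seealso [fit_bias()], [r2_decompose()], [predict.calibfit()],
#'   [adjusted_r2()]
#' @export
#' @examples
#' ch <- simulate_cohort(cohort_config(n = 200, seed = 3))
#' at <- build_analysis_table(ch)
#' fit <- fit_calibration(at, "energy", instruments = "ffq")
#' fit$r2_total
fit_calibration <- function(data, nutrient,
                            instruments = .instruments,
                            psychosocial = TRUE) {
  des <- .assemble_design(data, nutrient, instruments, psychosocial,
                          type = "calibration")
  out <- .ols_from_design(des)
  out$groups <- des$groups
  out$centers <- des$centers
  out$ids <- des$ids
  out$X <- des$X
  out$y <- des$y
  out$nutrient <- nutrient
  out$instruments <- des$instruments
  out$psychosocial <- psychosocial
  out$call <- match.call()
  class(out) <- "calibfit"
  out
}

#' Fit a bias regression
#'
#' Ordinary least squares of the reporting error — log self-report minus log
#' biomarker — of one instrument on the covariate design (centered BMI and
#' age, race, and the categorized factors; no self-report predictor).
#' Positive coefficients indicate over-reporting in that stratum relative to
#' the reference.
#'
#' @inheritParams fit_calibration
#' @param instrument The self-report instrument whose error is modelled.
#' @return An object of class `biasfit` (shares the `calibfit` methods
#'   except prediction and R2 decomposition).
#' @export
fit_bias <- function(data, instrument, nutrient, psychosocial = TRUE) {
  des <- .assemble_design(data, nutrient, instruments = character(),
                          psychosocial = psychosocial,
                          type = "bias", bias_instrument = instrument)
  out <- .ols_from_design(des)
  out$r2_groups <- NULL   # the bias tables report coefficients only
  out$r2_total <- if (out$sst > 0) 100 * (1 - out$rss / out$sst) else 0
  out$groups <- des$groups
  out$centers <- des$centers
  out$ids <- des$ids
  out$X <- des$X
  out$y <- des$y
  out$nutrient <- nutrient
  out$instrument <- instrument
  out$psychosocial <- psychosocial
  out$call <- match.call()
  class(out) <- c("biasfit", "calibfit")
  out
}

#' Sequential R2 decomposition over predictor groups
#'
#' Returns the sequential (type-I) contribution of each predictor group: the
#' increase in R2 when the group enters after all preceding groups. With the
#' default order this reproduces the decomposition stored in the fit; an
#' alternative entry order refits the sequence accordingly. Contributions
#' always sum to the total R2 of the full model.
#'
#' @param fit A `calibfit`.
#' @param order Character vector permuting `names(fit$groups)`.
#' @return A data.frame with `group`, `df` and `r2` (percent), plus the
#'   total as attribute `"r2_total"`.
#' @export
r2_decompose <- function(fit, order = names(fit$groups)) {
  stopifnot(inherits(fit, "calibfit"))
  if (!setequal(order, names(fit$groups)) ||
      length(order) != length(fit$groups))
    stop("order must be a permutation of the fitted predictor groups",
         call. = FALSE)
  groups <- fit$groups[order]
  cols <- c("(Intercept)", unlist(groups, use.names = FALSE))
  X <- fit$X[, cols, drop = FALSE]
  qrX <- qr(X)
  eff <- qr.qty(qrX, fit$y)
  col_ss <- eff[seq_len(ncol(X))]^2
  names(col_ss) <- cols
  r2 <- vapply(groups, function(cn) 100 * sum(col_ss[cn]) / fit$sst,
               numeric(1))
  out <- data.frame(group = names(groups),
                    df = lengths(groups),
                    r2 = unname(r2), row.names = NULL)
  structure(out, r2_total = sum(r2))
}

#' Predict calibrated intake
#'
#' Evaluates the fitted calibration equation on new participants, giving the
#' calibrated (biomarker-anchored) log intake. Continuous predictors are
#' centered at the means stored from the training sample, so predictions for
#' new data are on the training scale.
#'
#' @param object A `calibfit`.
#' @param newdata An analysis table containing the fit's self-report, BMI,
#'   age, race and category columns; defaults to the training rows.
#' @param ... Unused.
#' @return Numeric vector of calibrated log intakes.
#' @export
predict.calibfit <- function(object, newdata = NULL, ...) {
  if (inherits(object, "biasfit"))
    stop("prediction is defined for calibration fits only", call. = FALSE)
  if (is.null(newdata)) return(object$fitted)
  X <- .newdata_design(object, newdata)
  drop(X %*% object$coefficients)
}

.newdata_design <- function(object, newdata) {
  cols <- list()
  for (ins in object$instruments) {
    qc <- paste0("logq_", ins, "_", object$nutrient)
    if (is.null(newdata[[qc]]) || anyNA(newdata[[qc]]))
      stop("newdata is missing predictor ", qc, call. = FALSE)
    cols[[paste0("log_", .instrument_labels[ins], "_c")]] <-
      newdata[[qc]] - object$centers[qc]
  }
  for (v in c("bmi", "age")) {
    if (is.null(newdata[[v]]) || anyNA(newdata[[v]]))
      stop("newdata is missing predictor ", v, call. = FALSE)
    cols[[paste0(v, "_c")]] <- newdata[[v]] - object$centers[v]
  }
  race <- as.character(newdata$race)
  cols[["race_black"]] <- as.numeric(race == "Black")
  cols[["race_hispanic"]] <- as.numeric(race == "Hispanic")
  cols[["race_other"]] <- as.numeric(race %in%
                                       c("Asian/Pacific Islander", "Other"))
  if (isTRUE(object$psychosocial)) {
    for (f in .factors) {
      cc <- paste0("cat_", f)
      if (is.null(newdata[[cc]]) || anyNA(newdata[[cc]]))
        stop("newdata is missing predictor ", cc, call. = FALSE)
      cols[[paste0(f, "_M")]] <- as.numeric(newdata[[cc]] == "M")
      cols[[paste0(f, "_H")]] <- as.numeric(newdata[[cc]] == "H")
    }
  }
  X <- cbind("(Intercept)" = 1, do.call(cbind, cols))
  X[, names(object$coefficients), drop = FALSE]
}

#' @export
coef.calibfit <- function(object, ...) object$coefficients

#' @export
fitted.calibfit <- function(object, ...) object$fitted

#' @export
residuals.calibfit <- function(object, ...) object$residuals

#' Simulate responses from a fitted calibration equation
#'
#' Parametric simulation: new log-biomarker responses are drawn as the fitted
#' linear predictor plus Gaussian noise with the residual standard deviation.
#'
#' @param object A `calibfit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, one simulated response per
#'   training row.
#' @export
simulate.calibfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, object$sigma),
                                 simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.calibfit <- function(x, digits = 4, ...) {
  if (inherits(x, "biasfit")) {
    cat(sprintf("Bias regression: log(%s) - log(biomarker), %s\n",
                .instrument_labels[x$instrument],
                tolower(.nutrient_labels[x$nutrient])))
  } else {
    cat(sprintf("Calibration equation: log(biomarker %s) ~ %s + covariates\n",
                tolower(.nutrient_labels[x$nutrient]),
                paste(.instrument_labels[x$instruments], collapse = " + ")))
  }
  cat(sprintf("  n = %d, residual SD = %.4f, total R2 = %.2f%%\n",
              x$n, x$sigma, x$r2_total))
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.calibfit <- function(object, ...) {
  tab <- data.frame(beta = object$coefficients, se = object$se,
                    t = object$tvalues, p = object$pvalues,
                    sig = ifelse(object$pvalues < 0.05, "*", ""))
  out <- list(coefficients = tab, r2_total = object$r2_total,
              r2_groups = object$r2_groups, n = object$n,
              sigma = object$sigma, object = object)
  class(out) <- "summary.calibfit"
  out
}

#' @export
print.summary.calibfit <- function(x, digits = 4, ...) {
  print(x$object)
  cat("\nCoefficient table (\"*\" flags p < 0.05):\n")
  tab <- x$coefficients
  tab[, 1:4] <- round(tab[, 1:4], digits)
  print(tab)
  if (!is.null(x$r2_groups)) {
    cat("\nSequential R2 contributions (%):\n")
    print(round(x$r2_groups, 3))
    cat(sprintf("Total: %.3f%%\n", x$r2_total))
  }
  invisible(x)
}

#' Plot the sequential R2 decomposition
#'
#' Bar plot of each predictor group's sequential contribution to the total
#' R2 of a calibration equation.
#'
#' @param x A `calibfit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.calibfit <- function(x, ...) {
  if (is.null(x$r2_groups))
    stop("no R2 decomposition stored for this fit", call. = FALSE)
  labs <- names(x$r2_groups)
  pretty <- c(bmi = "BMI", age = "Age", race = "Race", .factor_labels)
  labs <- ifelse(startsWith(labs, "selfreport_"),
                 .instrument_labels[sub("selfreport_", "", labs)],
                 pretty[labs])
  graphics::barplot(x$r2_groups, names.arg = labs, las = 2,
                    ylab = expression("sequential " * R^2 * " (%)"),
                    main = sprintf("%s: total R2 = %.1f%%",
                                   .nutrient_labels[x$nutrient],
                                   x$r2_total), ...)
  invisible(x)
}
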