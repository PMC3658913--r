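# Reliability-replicate adjusted R2: converting the calibration R2 (variance
# of the log biomarker W explained) into the fraction of latent-intake
# variance var(Z) explained, using the replicate biomarker subsample and an
# assumed correlation rho between the primary and replicate errors.

#' Reliability-replicate summary statistics
#'
#' Computes, for one nutrient, the sample correlation of the primary and
#' reliability log biomarkers and the variance of their difference over the
#' replicate subsample, and the variance of the primary log biomarker over
#' the full sample.
#'
#' @param data An analysis table from [build_analysis_table()] (needs the
#'   `logw_*` and `logw2_*` columns), or any data.frame with those columns.
#' @param nutrient `"energy"`, `"protein"` or `"pdens"`.
#' @return An object of class `reliability_stats`: list with `n_pairs`,
#'   `corr_w1w2`, `var_diff`, `var_w` and `nutrient`.
#' @export
reliability_stats <- function(data, nutrient) {
  stopifnot(nutrient %in% .nutrients)
  w1 <- data[[paste0("logw_", nutrient)]]
  w2 <- data[[paste0("logw2_", nutrient)]]
  pair <- !is.na(w1) & !is.na(w2)
  if (sum(pair) < 3)
    stop("need at least 3 replicate pairs", call. = FALSE)
  out <- list(n_pairs = sum(pair),
              corr_w1w2 = stats::cor(w1[pair], w2[pair]),
              var_diff = stats::var(w1[pair] - w2[pair]),
              var_w = stats::var(w1[!is.na(w1)]),
              nutrient = nutrient)
  class(out) <- "reliability_stats"
  out
}

#' @export
print.reliability_stats <- function(x, ...) {
  cat(sprintf("Reliability replicate statistics (%s): %d pairs\n",
              tolower(.nutrient_labels[x$nutrient]), x$n_pairs))
  cat(sprintf("  corr(W1, W2) = %.4f,  var(W1 - W2) = %.5f,  var(W1) = %.5f\n",
              x$corr_w1w2, x$var_diff, x$var_w))
  invisible(x)
}

#' Adjusted R2: fraction of latent-intake variance explained
#'
#' Divides a calibration R2 by
#' `corr(W1, W2) - 0.5 * rho * var(W1 - W2) / ((1 - rho) * var(W))`,
#' where `rho` is the assumed correlation between the primary and replicate
#' biomarker errors. Under the classical model `W = Z + e` the denominator
#' equals `var(Z)/var(W)`, so the adjusted value is interpreted as the
#' percentage of variation in the latent intake `Z` explained by the
#' calibration equation. At `rho = 0` it reduces to `R2 / corr(W1, W2)`.
#'
#' @param r2 Calibration R2 in percent, or a `calibfit` (its `r2_total` is
#'   used).
#' @param stats A [reliability_stats()] object.
#' @param rho Assumed replicate-error correlation in (-1, 1); negative values
#'   reflect diet differing more between the two collection periods than
#'   within.
#' @return An object of class `adjusted_r2`: list with `r2`, `rho`,
#'   `denominator`, `adjusted_r2` (percent) and logical `exceeds_100`
#'   (flagged, not clamped).
#' @export
#' @examples
#' st <- structure(list(n_pairs = 88, corr_w1w2 = 0.8, var_diff = 0.02,
#'                      var_w = 0.05, nutrient = "energy"),
#'                 class = "reliability_stats")
#' adjusted_r2(40, st, rho = 0)$adjusted_r2  # 50
adjusted_r2 <- function(r2, stats, rho = 0) {
  if (inherits(r2, "calibfit")) r2 <- r2$r2_total
  stopifnot(inherits(stats, "reliability_stats"))
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  if (r2 < 0 || r2 > 100)
    stop("r2 must be a percentage in [0, 100]", call. = FALSE)
  den <- stats$corr_w1w2 -
    0.5 * rho * stats$var_diff / ((1 - rho) * stats$var_w)
  if (!is.finite(den) || den <= 0)
    stop("non-positive denominator: the assumed rho is inconsistent with ",
         "the replicate statistics", call. = FALSE)
  adj <- r2 / den
  out <- list(r2 = r2, rho = rho, denominator = den, adjusted_r2 = adj,
              exceeds_100 = adj > 100, nutrient = stats$nutrient)
  class(out) <- "adjusted_r2"
  out
}

#' @export
print.adjusted_r2 <- function(x, ...) {
  cat(sprintf("Adjusted R2 (%s, rho = %.2f): %.2f%% / %.4f = %.2f%%%s\n",
              tolower(.nutrient_labels[x$nutrient]), x$rho, x$r2,
              x$denominator, x$adjusted_r2,
              if (x$exceeds_100) "  [exceeds 100%]" else ""))
  invisible(x)
}

#' Sensitivity of the adjusted R2 to the replicate-error correlation
#'
#' Evaluates [adjusted_r2()] over a grid of assumed `rho` values, optionally
#' with the incremental adjusted contribution of a covariate block computed
#' as the difference between the adjusted R2 of a full and a reduced
#' calibration equation at the same `rho`.
#'
#' @param r2 Full-model R2 in percent, or a `calibfit`.
#' @param stats A [reliability_stats()] object.
#' @param rho Numeric grid of assumed correlations, each in (-1, 1);
#'   default `c(0, -0.1, -0.2)`.
#' @param r2_reduced Optional reduced-model R2 (percent) or `calibfit`; when
#'   given, the output gains the incremental adjusted contribution
#'   `adjusted(full) - adjusted(reduced)`.
#' @return A data.frame with one row per `rho`: `rho`, `r2`, `denominator`,
#'   `adjusted_r2` and (if `r2_reduced` is given) `r2_reduced`,
#'   `adjusted_r2_reduced`, `incremental`.
#' @export
rho_sensitivity <- function(r2, stats, rho = c(0, -0.1, -0.2),
                            r2_reduced = NULL) {
  if (inherits(r2, "calibfit")) r2 <- r2$r2_total
  if (inherits(r2_reduced, "calibfit")) r2_reduced <- r2_reduced$r2_total
  rows <- lapply(rho, function(r) {
    a <- adjusted_r2(r2, stats, r)
    row <- data.frame(rho = r, r2 = r2, denominator = a$denominator,
                      adjusted_r2 = a$adjusted_r2)
    if (!is.null(r2_reduced)) {
      ar <- adjusted_r2(r2_reduced, stats, r)
      row$r2_reduced <- r2_reduced
      row$adjusted_r2_reduced <- ar$adjusted_r2
      row$incremental <- a$adjusted_r2 - ar$adjusted_r2
    }
    row
  })
  do.call(rbind, rows)
}
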