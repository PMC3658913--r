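# Bootstrap comparison of nested calibration equations: standard error and
# p-value for the difference in total R2 with and without a covariate block.

# Fast R2 of y on X (intercept included in X) for resampled rows; drops
# all-constant columns so degenerate resamples (an empty category level)
# still fit.
.boot_r2 <- function(X, y) {
  fit <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
  degenerate <- FALSE
  if (is.null(fit) || fit$rank < ncol(X)) {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(col) stats::sd(col) > 0))
    X <- X[, keep, drop = FALSE]
    fit <- .lm.fit(X, y)
    degenerate <- TRUE
  }
  sst <- sum((y - mean(y))^2)
  r2 <- 100 * (1 - sum(fit$residuals^2) / sst)
  c(r2 = r2, degenerate = as.numeric(degenerate))
}

#' Bootstrap inference for the change in R2 between nested calibration models
#'
#' Fits the full calibration equation and the reduced equation without one
#' covariate block on the same complete-case rows, then resamples
#' participants with replacement `B` times, refitting both equations per
#' resample. The standard error is the SD of the bootstrap R2 differences
#' and the p-value comes from a two-sided normal (Wald) approximation
#' `z = delta_observed / SE`; a basic (reverse-percentile) interval p-value
#' is available via `p_method = "percentile"`. Category cut-offs and outlier exclusions are
#' frozen from the original analysis table; resamples with an empty category
#' level are refit after dropping the empty column and counted.
#'
#' @param data An analysis table from [build_analysis_table()].
#' @param nutrient `"energy"`, `"protein"` or `"pdens"`.
#' @param instruments Instruments in both equations (default all three).
#' @param block Covariate block dropped in the reduced model; currently
#'   `"psychosocial"` (the six categorized factors).
#' @param B Number of bootstrap resamples (default 5000).
#' @param seed Seed for the resampling (required for reproducibility).
#' @param p_method `"normal"` (default) or `"percentile"`.
#' @return An object of class `boot_delta_r2`: list with `delta_r2`
#'   (observed, percent), `se`, `p_value`, `r2_full`, `r2_reduced`, `B`,
#'   `n`, `n_degenerate`, `seed` and the bootstrap draws `delta_boot`.
#' @export
#' @examples
#' ch <- simulate_cohort(cohort_config(n = 150, seed = 11))
#' at <- build_analysis_table(ch)
#' bt <- bootstrap_delta_r2(at, "energy", instruments = "ffq",
#'                          B = 100, seed = 1)
#' bt$p_value
bootstrap_delta_r2 <- function(data, nutrient,
                               instruments = .instruments,
                               block = "psychosocial",
                               B = 5000, seed = NULL,
                               p_method = c("normal", "percentile")) {
  p_method <- match.arg(p_method)
  block <- match.arg(block)
  full <- .assemble_design(data, nutrient, instruments,
                           psychosocial = TRUE, type = "calibration")
  # reduced model on the *same* rows as the full model
  sub <- data[match(full$ids, data$participant_id), , drop = FALSE]
  red <- .assemble_design(sub, nutrient, instruments,
                          psychosocial = FALSE, type = "calibration")
  stopifnot(identical(full$ids, red$ids))
  n <- length(full$y)
  r2_full <- .boot_r2(full$X, full$y)["r2"]
  r2_red <- .boot_r2(red$X, red$y)["r2"]
  delta_obs <- unname(r2_full - r2_red)
  if (delta_obs < -1e-8)
    stop("observed delta R2 is negative; models are not nested on ",
         "identical rows", call. = FALSE)

  if (!is.null(seed)) set.seed(as.integer(seed))
  delta_boot <- numeric(B)
  n_degen <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- full$y[idx]
    rf <- .boot_r2(full$X[idx, , drop = FALSE], yb)
    rr <- .boot_r2(red$X[idx, , drop = FALSE], yb)
    if (rf["degenerate"] > 0 || rr["degenerate"] > 0)
      n_degen <- n_degen + 1L
    delta_boot[b] <- rf["r2"] - rr["r2"]
  }
  if (n_degen > 0.01 * B)
    stop(sprintf("rank deficiency in %d of %d resamples (> 1%%); ",
                 n_degen, B),
         "category levels are too sparse for a stable bootstrap",
         call. = FALSE)
  se <- stats::sd(delta_boot)
  p <- if (se == 0) 1 else switch(
    p_method,
    normal = 2 * stats::pnorm(-abs(delta_obs / se)),
    # basic (reverse-percentile) construction: the two-sided basic interval
    # excludes 0 at level alpha iff the upper bootstrap quantile is below
    # 2 * delta_obs
    percentile = min(1, 2 * mean(delta_boot >= 2 * delta_obs))
  )
  out <- list(nutrient = nutrient, instruments = instruments, block = block,
              delta_r2 = delta_obs, se = se, p_value = p,
              r2_full = unname(r2_full), r2_reduced = unname(r2_red),
              B = B, n = n, n_degenerate = n_degen, seed = seed,
              p_method = p_method, delta_boot = delta_boot)
  class(out) <- "boot_delta_r2"
  out
}

#' @export
print.boot_delta_r2 <- function(x, ...) {
  cat(sprintf("Bootstrap comparison of nested calibration equations (%s)\n",
              tolower(.nutrient_labels[x$nutrient])))
  cat(sprintf("  full R2 = %.3f%%, reduced R2 = %.3f%% (block dropped: %s)\n",
              x$r2_full, x$r2_reduced, x$block))
  cat(sprintf("  delta R2 = %.3f%%, bootstrap SE = %.3f (B = %d), p = %.4g\n",
              x$delta_r2, x$se, x$B, x$p_value))
  if (x$n_degenerate > 0)
    cat(sprintf("  %d degenerate resample(s) refit after dropping empty columns\n",
                x$n_degenerate))
  invisible(x)
}
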