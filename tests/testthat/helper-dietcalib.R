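# Shared fixtures and independent oracles, built in code at test time.

# Default config with the psychosocial bias coefficients removed from every
# instrument: the six-factor block is inert in the self-report model.
null_psych_config <- function(n = 450, ...) {
  cfg <- cohort_config(n = n, ...)
  for (ins in names(cfg$selfreport)) {
    for (nu in names(cfg$selfreport[[ins]])) {
      co <- cfg$selfreport[[ins]][[nu]]$coefs
      cfg$selfreport[[ins]][[nu]]$coefs <- co[!grepl("_M$|_H$", names(co))]
    }
  }
  cfg
}

# Power-scenario config: inert block everywhere except a +/-0.4 bias on the
# six high-category dummies of the 4DFR energy report (effect size fixed by a
# plug-in population-R2 calculation; see the methods vignette).
power_psych_config <- function(n = 450, gamma = 0.4, ...) {
  cfg <- null_psych_config(n = n, ...)
  cfg$selfreport$dfr4$energy$coefs <- c(
    cfg$selfreport$dfr4$energy$coefs,
    c(socdes_H = -gamma, meals_H = gamma, emo_H = gamma,
      unc_H = -gamma, body_H = gamma, restraint_H = -gamma))
  cfg
}

small_table <- function(n = 200, seed = 3, config = cohort_config(n = n)) {
  config$seed <- as.integer(seed)
  config$n <- as.integer(n)
  build_analysis_table(simulate_cohort(config))
}

# Tiny-instance fixture with balanced race strata so every dummy column is
# non-constant even at n = 50.
tiny_table <- function(n = 50, seed = 3) {
  w <- c("Non-Hispanic White" = 0.3, "Black" = 0.25, "Hispanic" = 0.25,
         "Asian/Pacific Islander" = 0.1, "Other" = 0.1)
  small_table(n, seed, config = cohort_config(n = n, race_weights = w))
}

# Independent OLS oracle: normal equations.
ne_ols <- function(X, y) {
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coefficients = drop(beta),
       se = sqrt(sigma2 * diag(solve(xtx))))
}

# Independent sequential-R2 oracle: nested lm() refits over cumulative
# predictor groups.
nested_r2_oracle <- function(fit) {
  X <- fit$X
  y <- fit$y
  r2 <- numeric(length(fit$groups))
  prev <- 0
  cols <- "(Intercept)"
  for (i in seq_along(fit$groups)) {
    cols <- c(cols, fit$groups[[i]])
    m <- stats::lm(y ~ X[, setdiff(cols, "(Intercept)"), drop = FALSE])
    cur <- 100 * summary(m)$r.squared
    r2[i] <- cur - prev
    prev <- cur
  }
  stats::setNames(r2, names(fit$groups))
}
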