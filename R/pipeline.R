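# End-to-end orchestration: simulate (or load) a cohort, derive the analysis
# table, fit bias and calibration regressions for all nutrients and
# instruments, run the adjusted-R2 sensitivity and the bootstrap nested-model
# comparisons, and write every table plus a machine-readable run manifest.

#' Pairwise correlations among the psychosocial and diet-behavior factors
#'
#' Pearson correlation and two-sided p-value for every pair of the six
#' factor scores, using pairwise-complete observations.
#'
#' @param scores A data.frame with the six factor columns (`meals`, `body`,
#'   `restraint`, `unc`, `emo`, `socdes`), e.g. the `psychosocial` element
#'   of a cohort or an analysis table.
#' @return A data.frame with `factor1`, `factor2`, `r`, `p`, `n`.
#' @export
pairwise_correlations <- function(scores) {
  stopifnot(all(.factors %in% names(scores)))
  pairs <- utils::combn(.factors, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- scores[[pr[1]]]
    y <- scores[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3)
      stop("fewer than 3 complete pairs for ", pr[1], "-", pr[2],
           call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("constant column: ", pr[1], " or ", pr[2], call. = FALSE)
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(factor1 = pr[1], factor2 = pr[2],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Table-1-style descriptives of the analysis sample.
.descriptives <- function(at) {
  qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
  rows <- list(
    data.frame(variable = "age", statistic = c("median", "q1", "q3"),
               value = unname(qs(at$age))),
    data.frame(variable = "bmi", statistic = c("median", "q1", "q3"),
               value = unname(qs(at$bmi)))
  )
  race_n <- table(at$race)
  rows[[length(rows) + 1]] <-
    data.frame(variable = paste0("race_", names(race_n)),
               statistic = "n", value = as.numeric(race_n))
  for (f in .factors) {
    rows[[length(rows) + 1]] <-
      data.frame(variable = f, statistic = c("median", "q1", "q3"),
                 value = unname(qs(at[[f]])))
    rows[[length(rows) + 1]] <-
      data.frame(variable = paste0("cat_", f),
                 statistic = c("n_L", "n_M", "n_H"),
                 value = as.numeric(table(at[[paste0("cat_", f)]])))
  }
  do.call(rbind, rows)
}

.coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients),
             se = unname(fit$se),
             p = unname(fit$pvalues),
             sig = ifelse(fit$pvalues < 0.05, "*", ""),
             row.names = NULL)
}

.calib_table <- function(fit) {
  tab <- .coef_table(fit)
  grp <- rep(NA_character_, nrow(tab))
  for (g in names(fit$groups))
    grp[tab$term %in% fit$groups[[g]]] <- g
  tab$group <- grp
  dec <- r2_decompose(fit)
  tab$group_r2 <- dec$r2[match(tab$group, dec$group)]
  # report each group's R2 on its first row only, as in the printed tables
  dup <- duplicated(tab$group) | is.na(tab$group)
  tab$group_r2[dup] <- NA
  tab
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or uses one supplied), builds the analysis table, and
#' produces every output of the analysis: descriptives, factor
#' inter-correlations, bias regressions (three instruments x three
#' nutrients), calibration equations (each instrument separately and all
#' three combined) with sequential R2 decomposition, the adjusted-R2
#' sensitivity over the configured rho grid, bootstrap nested-model
#' comparisons for the psychosocial block, and a JSON run manifest. A rerun
#' with the same config and seed reproduces every output byte for byte.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory for the CSV tables and manifest; `NULL`
#'   skips writing.
#' @param seed Master seed (overrides `config$seed`).
#' @param cohort Optional pre-built `dietcal_cohort`; when supplied, the
#'   simulation stage is skipped and `config` governs only the analysis
#'   (bootstrap size, rho grid).
#' @param cutoffs Categorization mode passed to [build_analysis_table()].
#' @param bootstrap Run the bootstrap comparisons (default `TRUE`).
#' @return Invisibly, a list with `cohort`, `analysis_table`,
#'   `correlations`, `bias` (list by nutrient/instrument), `calibration`
#'   (list by nutrient/instrument set), `reliability`, `adjusted`
#'   (rho-sensitivity tables), `comparisons`, and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         seed = NULL, cohort = NULL,
                         cutoffs = "printed", bootstrap = TRUE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d elapsed=%.1fs", stage, n_in, n_out,
                    proc.time()[["elapsed"]] - t0))

  if (is.null(cohort)) cohort <- simulate_cohort(config)
  log_stage("simulate", config$n, nrow(cohort$participants))

  at <- build_analysis_table(cohort, cutoffs = cutoffs)
  excl <- attr(at, "exclusions")
  log_stage("preprocess", nrow(cohort$participants), nrow(at))

  correlations <- pairwise_correlations(at)
  descr <- .descriptives(at)

  bias <- list()
  calibration <- list()
  adjusted <- list()
  reliability <- list()
  for (nu in .nutrients) {
    for (ins in .instruments)
      bias[[paste(nu, ins, sep = "_")]] <- fit_bias(at, ins, nu)
    for (set in c(as.list(.instruments), list(.instruments))) {
      key <- paste(nu, paste(set, collapse = "+"), sep = "_")
      calibration[[key]] <- fit_calibration(at, nu, instruments = set)
    }
    reliability[[nu]] <- reliability_stats(at, nu)
    full <- calibration[[paste(nu, paste(.instruments, collapse = "+"),
                               sep = "_")]]
    reduced <- fit_calibration(at, nu, instruments = .instruments,
                               psychosocial = FALSE)
    adjusted[[nu]] <- cbind(nutrient = nu,
                            rho_sensitivity(full, reliability[[nu]],
                                            rho = config$rho_grid,
                                            r2_reduced = reduced))
  }
  log_stage("fit", nrow(at), length(bias) + length(calibration))

  comparisons <- NULL
  if (bootstrap) {
    bseed <- if (!is.null(config$seed))
      stage_seed(config$seed, "bootstrap") else NULL
    rows <- lapply(.nutrients, function(nu) {
      bt <- bootstrap_delta_r2(at, nu, instruments = .instruments,
                               B = config$n_bootstrap,
                               seed = if (is.null(bseed)) NULL else
                                 stage_seed(bseed, nu))
      data.frame(nutrient = nu,
                 model_pair = "psychosocial block vs none",
                 delta_r2 = bt$delta_r2, se = bt$se, p = bt$p_value,
                 B = bt$B, seed = if (is.null(bt$seed)) NA else bt$seed,
                 n_degenerate = bt$n_degenerate)
    })
    comparisons <- do.call(rbind, rows)
    log_stage("bootstrap", nrow(at), nrow(comparisons))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietcalib")),
    master_seed = config$seed,
    stage_seeds = if (!is.null(config$seed))
      lapply(stats::setNames(nm = c("participants", "psychosocial",
                                    "latent_intake", "biomarkers",
                                    "self_reports", "bootstrap")),
             function(s) stage_seed(config$seed, s)) else NULL,
    n_participants = nrow(cohort$participants),
    n_reliability = sum(cohort$participants$reliability),
    n_analysis_rows = nrow(at),
    n_exclusions = nrow(excl),
    n_bootstrap = if (bootstrap) config$n_bootstrap else 0L,
    rho_grid = config$rho_grid,
    outputs = character()
  )

  result <- list(cohort = cohort, analysis_table = at,
                 correlations = correlations, descriptives = descr,
                 bias = bias, calibration = calibration,
                 reliability = reliability, adjusted = adjusted,
                 comparisons = comparisons, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(obj, path, row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, name)
    }
    write_cohort(cohort, out_dir)
    manifest$outputs <- c(manifest$outputs, "participants.csv",
                          "psychosocial.csv", "intake_truth.csv",
                          "biomarkers.csv", "selfreports.csv")
    wr(at, "analysis_table.csv")
    wr(excl, "exclusions.csv")
    wr(descr, "table1_descriptives.csv")
    wr(correlations, "correlations.csv")
    for (nu in .nutrients) {
      btabs <- lapply(.instruments, function(ins)
        cbind(instrument = unname(.instrument_labels[ins]),
              .coef_table(bias[[paste(nu, ins, sep = "_")]])))
      wr(do.call(rbind, btabs), sprintf("bias_%s.csv", nu))
      for (set in c(as.list(.instruments), list(.instruments))) {
        key <- paste(nu, paste(set, collapse = "+"), sep = "_")
        fname <- sprintf("calibration_%s_%s.csv", nu,
                         if (length(set) == 3) "combined" else set)
        wr(.calib_table(calibration[[key]]), fname)
      }
      wr(adjusted[[nu]], sprintf("adjusted_r2_%s.csv", nu))
    }
    if (!is.null(comparisons)) wr(comparisons, "comparisons.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}
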