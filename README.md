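# dietcalib

Biomarker calibration of self-reported dietary intake, with psychosocial
and diet-behavior covariates.

## What problem this package addresses

Self-reported diet — food frequency questionnaires (FFQ), four-day food
records (4DFR), 24-hour recalls (24HR) — measures true intake with
systematic and random error, which biases diet–disease association
estimates. In validation studies, *recovery biomarkers* (doubly labeled
water for energy, urinary nitrogen for protein) give objective anchors
whose error is plausibly classical. dietcalib is for biostatisticians and
nutritional epidemiologists working with such validation data: it fits the
bias and regression-calibration equations that correct self-report, and
quantifies how much psychosocial characteristics — social desirability,
body-image discordance, the TFEQ-R18 eating scales, percent of meals eaten
at home — contribute to reporting error and to calibration precision.

Because participant-level data of the motivating study are not public, the
package ships a synthetic-cohort generator that emulates the study's
structure (450 postmenopausal women with oversampled strata, an 88-woman
reliability subsample, score distributions matching the published moments),
so the entire pipeline is testable against known ground truth.

## The models

On the log scale, the biomarker follows a classical measurement model and
self-report a flexible one:

    W = Z + e                          (biomarker)
    Q = S0 + S1 Z + S2 V + S3 V Z + r + u    (self-report)

with `Z` the latent log intake, `V` participant characteristics (BMI, age,
race/ethnicity, six categorized psychosocial/diet-behavior factors), `r` a
person-specific and `u` an occasion reporting error. The package fits:

* **bias regressions** `Q − W ~ V` per instrument and nutrient;
* **calibration equations** `W ~ Q + V` with a sequential (type-I) R²
  decomposition over predictor groups that sums exactly to the total;
* **adjusted R²** `R² / [corr(W1,W2) − 0.5 ρ var(W1−W2)/((1−ρ) var(W))]`,
  which under the classical model rescales R² by var(Z)/var(W) — the
  fraction of *latent-intake* variance explained — with sensitivity over
  the assumed replicate-error correlation ρ;
* **bootstrap ΔR² inference** comparing nested calibration equations with
  and without the psychosocial block.

## Worked example

```r
library(dietcalib)

ch  <- simulate_cohort(cohort_config(n = 450, seed = 20))
at  <- build_analysis_table(ch)          # logs, outlier screen, categories
fit <- fit_calibration(at, "energy", instruments = "ffq")
fit
#> Calibration equation: log(biomarker energy) ~ FFQ + covariates
#>   n = 450, residual SD = 0.1820, total R2 = 33.59%

summary(fit)   # coefficient table plus, per predictor group:
#> Sequential R2 contributions (%):
#> selfreport_ffq            bmi            age           race          meals
#>          3.250         17.268         10.137          0.637          0.237
#>           body      restraint            unc            emo         socdes
#>          1.296          0.025          0.202          0.177          0.364
#> Total: 33.592%

st <- reliability_stats(at, "energy")
st
#> Reliability replicate statistics (energy): 88 pairs
#>   corr(W1, W2) = 0.5715,  var(W1 - W2) = 0.03538,  var(W1) = 0.04789
adjusted_r2(fit, st, rho = -0.1)
#> Adjusted R2 (energy, rho = -0.10): 33.59% / 0.6051 = 55.52%

bootstrap_delta_r2(at, "energy", instruments = "ffq", B = 2000, seed = 1)
#> Bootstrap comparison of nested calibration equations (energy)
#>   full R2 = 33.592%, reduced R2 = 31.292% (block dropped: psychosocial)
#>   delta R2 = 2.301%, bootstrap SE = 1.280 (B = 2000), p = 0.07232
```

Reading the output: the FFQ alone explains 3.3% of biomarker variance while
BMI and age dominate (17.3% and 10.1%); the six psychosocial/diet-behavior
groups together add about 2.3 percentage points, with a borderline
bootstrap p-value. Dividing by the reliability-based denominator (0.605 at
ρ = −0.1) converts the 33.6% of *biomarker* variance explained into 55.5%
of *latent-intake* variance explained.

`fit_bias(at, "ffq", "energy")` gives the corresponding bias regression
(e.g. the high social-desirability stratum under-reports energy on the
FFQ), and `run_pipeline(cohort_config(seed = 1), out_dir = "out")` writes
every table — descriptives, correlations, bias and calibration tables per
nutrient and instrument, the adjusted-R² sensitivity, bootstrap
comparisons — plus a JSON run manifest that makes the run byte-for-byte
reproducible.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dietcalib.R", package="dietcalib"))')" \
    run --out out --seed 1
```

## Package layout

* `R/config.R`, `R/cohort.R` — study configuration and the synthetic
  cohort generator (models above, hierarchical seeding).
* `R/scoring.R` — Crowne-Marlowe, TFEQ-R18, silhouette-discordance and
  meals-at-home scoring; fixed and tertile categorization.
* `R/preprocess.R` — protein density, interquartile outlier rule,
  centering, design construction.
* `R/calibration.R` — `fit_bias()` / `fit_calibration()` (classed S3 fits
  with `print`, `summary`, `coef`, `predict`, `residuals`, `simulate`,
  `plot` methods) and `r2_decompose()`.
* `R/variance.R`, `R/bootstrap.R` — adjusted R² with ρ-sensitivity;
  nested-model bootstrap.
* `R/pipeline.R` — `run_pipeline()` and the factor correlation table.
* `vignettes/calibration-methods.Rmd` — models, generator design,
  numerical choices, limitations.
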