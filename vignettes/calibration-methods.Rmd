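---
title: "Measurement-error models and calibration methods in dietcalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-error models and calibration methods in dietcalib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcalib)
```

## The problem

Self-reported dietary intake — from a food frequency questionnaire (FFQ), a
four-day food record (4DFR) or repeated 24-hour recalls (24HR) — carries
systematic and random error that distorts diet–disease association
estimates. Recovery biomarkers (doubly labeled water for energy expenditure,
urinary nitrogen for protein) provide objective anchors: their error is
plausibly *classical*, i.e. unbiased and independent of both true intake and
participant traits. Regression calibration uses a validation sample with
both kinds of measurement to build an equation predicting true intake from
self-report and participant characteristics; the calibrated intakes then
replace raw self-report in disease models.

dietcalib implements the full analysis around that idea for a validation
study of postmenopausal women, with particular attention to *psychosocial
and diet-behavior covariates*: social desirability, body-image discordance,
the three TFEQ-R18 eating scales (cognitive restraint, uncontrolled eating,
emotional eating), and the percent of meals eaten at home.

## Measurement models

All intakes are analysed on the log scale, where consumption is
approximately normally distributed. Two models drive everything:

* **Biomarker (classical):** \(W = Z + e\), where \(Z\) is the latent log
  intake over a short period and \(e\) is independent of \(Z\) and of all
  covariates. A reliability subsample repeats the protocol about six months
  later, giving \(W_1 = Z + e_1\) and \(W_2 = Z + e_2\) with
  \(\rho = \mathrm{corr}(e_1, e_2)\).
* **Self-report (flexible):**
  \(Q = S_0 + S_1 Z + S_2 V + S_3 V Z + r + u\), where \(V\) collects
  participant characteristics (BMI, age, race/ethnicity, and the six
  categorized psychosocial/diet-behavior factors), \(r\) is a
  person-specific reporting error and \(u\) an occasion error, all
  independent of \(Z\), \(V\) and \(e\).

Three analyses follow:

1. **Bias regressions** (`fit_bias()`): OLS of \(Q - W\) on \(V\), one per
   instrument and nutrient. A negative coefficient for, say, the high
   social-desirability category means that stratum under-reports relative
   to the low stratum.
2. **Calibration equations** (`fit_calibration()`): OLS of \(W\) on the
   centered \(Q\) (one column per instrument included) plus \(V\). The
   total \(R^2\) — the fraction of biomarker variance explained — is
   decomposed sequentially over predictor groups.
3. **Adjusted \(R^2\)** (`adjusted_r2()`): because \(W\) contains the
   error \(e\), no equation can explain all of \(\mathrm{var}(W)\); the
   quantity of scientific interest is the fraction of
   \(\mathrm{var}(Z)\) explained. Dividing \(R^2\) by
   \[
   \mathrm{corr}(W_1, W_2)
     \;-\; \frac{0.5\,\rho\,\mathrm{var}(W_1 - W_2)}{(1-\rho)\,\mathrm{var}(W)}
   \]
   achieves this: under the classical model the denominator equals
   \(\mathrm{var}(Z)/\mathrm{var}(W)\) for the assumed \(\rho\). The
   grouping of terms above is the only reading of the formula with that
   property (e.g. \(\mathrm{var}(Z) = 1\), \(\sigma_e^2 = 0.5\),
   \(\rho = -0.1\) gives \(\mathrm{corr} = 0.95/1.5\),
   \(\mathrm{var}(W_1-W_2) = 1.1\), denominator exactly \(2/3\)); the test
   suite enforces the identity by simulation. \(\rho\) cannot be estimated
   from the data, so `rho_sensitivity()` sweeps an assumed grid, by default
   \(\{0, -0.1, -0.2\}\) — negative values reflect diet differing more
   between the two collection periods than within either.

### Sequential R² decomposition

The per-group \(R^2\) columns are **type-I (sequential)** contributions in
the fixed entry order: self-report(s), BMI, age, race, meals at home, body
image, restraint, uncontrolled eating, emotional eating, social
desirability. Sequential attribution is the only scheme whose contributions
provably sum to the total \(R^2\) — the conservation property the printed
"Total" row relies on — and it falls out exactly of the QR factorization
used for the fit (the squared QR effects are the sequential sums of
squares). `r2_decompose()` recomputes the decomposition under any group
order; for correlated groups the allocation is order-dependent, which is
why the order is fixed and recorded.

### Categorization

Each factor is cut into low/medium/high. Body-image discordance uses the
fixed scheme <1 / 1–2 / ≥3. The other five use tertile-derived cut-offs;
`printed_cutoffs()` carries the study's fixed values (e.g. ≤19 / 20–24 /
>24 for social desirability — the published Crowne–Marlowe bands are not
usable here because almost nobody scores low) and is the default, while
`compute_tertile_cutoffs()` recomputes empirical tertiles. Tertiles use the
inverse-empirical-CDF quantile (`type = 1`), so cut-offs are observed score
values — integer scores give integer cut-offs, matching the printed style —
and intervals are closed on the right of the lower category, matching the
"≤" convention.

### Bootstrap comparison of nested equations

`bootstrap_delta_r2()` tests whether the six psychosocial/diet-behavior
groups add explained variance beyond self-report, BMI, age and race:
participants are resampled with replacement (the participant is the
resampling unit; cut-offs and outlier exclusions are frozen from the
original sample), both nested equations are refit per resample, the SE is
the SD of the bootstrap \(\Delta R^2\), and the default p-value is the
two-sided normal (Wald) approximation \(z = \Delta R^2_{\mathrm{obs}}/SE\)
with \(B = 5000\) resamples by default.

A known limitation: for nested models on identical rows
\(\Delta R^2 \ge 0\) on every resample, so the observed statistic sits at a
boundary and the Wald construction is anticonservative for
moderate-dimensional blocks (a twelve-column block at \(n = 450\) yields a
type-I error near 0.10 at nominal 0.05 in the package's own simulations —
a chi-square argument predicts exactly this order). The basic
(reverse-percentile) alternative (`p_method = "percentile"`) errs far in
the conservative direction. The Wald default is retained because it is the
construction the reported analyses use; its p-values should be read as
approximate.

## The synthetic cohort generator

No participant-level data from the original study are public, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, making every downstream stage testable against known
ground truth. The defaults are the study conditions:

* **Design**: \(n = 450\); 19.6% reliability subsample (88 participants);
  race/ethnicity weights 64.0/18.6/14.2/1.8/1.3% (Non-Hispanic White,
  Black, Hispanic, Asian/Pacific Islander, Other — the latter two merge
  into one dummy in all designs); age bands 59–69/69–79/79–91 with weights
  47.3/42.2/10.5%; BMI bands <25/25–30/≥30 with weights 34.7/26.9/38.4%,
  uniform within band. The oversampling design is represented as these
  configurable strata weights, not as a two-phase sampling estimator,
  because the analyses are unweighted.
* **Psychosocial scores**: a six-dimensional latent Gaussian with the
  reported means and SDs (meals at home 83.0 (13.0), body-image
  discordance 1.25 (1.06), restraint 15.24 (1.98), uncontrolled eating
  25.66 (3.47), emotional eating 8.47 (2.6), social desirability
  21.07 (5.35)); the correlation matrix carries every reported pairwise
  correlation (strongest: uncontrolled–emotional 0.60) with unreported
  pairs at zero, plus correlations with standardized BMI (−0.27 with
  uncontrolled, −0.40 with emotional eating). Discrete instrument supports
  are produced by scaling, rounding and clipping the latent Gaussian — the
  simplest mechanism that hits the printed moments; clipping shifts the
  emotional-eating mean down by about 0.1, the only visible distortion.
  The meals-at-home SD (13.0) is derived from the printed interquartile
  range under normality; it is not directly reported.
* **Latent intake**: bivariate log-normal; log energy mean 7.601
  (≈2000 kcal/d) and log protein mean 4.248 (≈70 g/d), with linear BMI and
  age dependence (energy: +0.015 per kg/m², −0.009 per year) sized so that
  BMI and age explain biomarker-variance shares of the order the
  calibration tables report. Protein energy is kept below total energy
  (4 kcal/g) by rejection. Residual SDs 0.134/0.212 and correlation 0.7
  are set so that \(\mathrm{var}(Z)/\mathrm{var}(W)\) lands near 0.6 for
  energy and 0.5 for protein, the regime the adjusted-\(R^2\) results
  imply.
* **Biomarkers**: classical error with log-scale SDs 0.13 (energy,
  doubly-labeled-water-like precision) and 0.25 (protein); replicate errors
  share the configured \(\rho\) (0 by default).
* **Self-reports**: per instrument × nutrient, slopes 0.45–0.8 (FFQ
  weakest, 4DFR strongest), negative intercept biases (under-reporting),
  person-specific plus occasion error variances largest for the FFQ, and
  sparse covariate-bias coefficients taken from the significant entries of
  the reported bias tables (e.g. −0.174 on the high social-desirability
  dummy and +0.181 on the high meals-at-home dummy for FFQ energy). The
  person-specific error \(r\) is shared across instruments within a
  participant and nutrient by default (configurable off): cross-instrument
  sharing is not identified by the study, and sharing lets tests probe the
  consequences of correlated errors. Interaction terms \(S_3 V Z\) are
  supported in the generator but omitted from the default fitted designs,
  mirroring the reported tables, which contain no interaction rows.

Protein density (percent of energy from protein, 4 kcal/g Atwater factor)
is derived from energy and protein at the analysis stage — for biomarkers
and for each instrument — rather than generated separately, which keeps the
three nutrients internally consistent by construction.

**What the generator does not emulate**: food-item-level responses and
nutrient-coding error; seasonal or period effects in the replicate beyond
\(\rho\); survey weights; non-Gaussian latent tails; item-level missingness
(missing scores simply propagate as missing). Passing tests therefore
demonstrate correctness of the *statistical machinery* under the assumed
models, not robustness of the original findings to violations of those
models.

Seeding is hierarchical: one master seed, with per-stage child seeds
derived deterministically from the stage name, so identical configurations
reproduce byte-identical tables and single stages can be rerun
independently.

## Numerical and design choices

* **Outlier rule**: values outside the interquartile range by more than
  three times its width are excluded, per variable, computed once on the
  full sample (single pass, not iterated). Screening is applied on the log
  (analysis) scale by default — the scale is not pinned down by the
  analysis description — with the raw scale reachable via
  `outlier_scale = "raw"`. A participant excluded for one variable remains
  eligible for every other analysis.
* **Centering**: BMI, age and the log self-reports are centered at the
  analysis-sample mean (stored for prediction); category dummies are never
  centered. Centering leaves slopes and the \(R^2\) decomposition
  unchanged and makes the intercept the expected log biomarker at the
  reference covariate pattern.
* **Rank deficiency**: designs are checked via QR rank; an empty category
  level is an error in a primary fit, while bootstrap resamples drop the
  empty column, count the event, and abort if more than 1% of resamples
  are affected.
* **Standard errors**: conventional single-fit OLS standard errors, with
  significance flagged at 0.05 and no multiple-testing correction,
  mirroring the reported tables; bootstrap SEs are reserved for the
  \(\Delta R^2\) comparison.
* **Reliability statistics**: \(\mathrm{corr}(W_1, W_2)\) and
  \(\mathrm{var}(W_1 - W_2)\) use the replicate subsample;
  \(\mathrm{var}(W)\) uses the full primary sample — the choice that uses
  all available information, as the split is not pinned down.

## Problem sizes used in the test suite

The package's statistical guarantees are exercised at sizes chosen to make
Monte-Carlo error small relative to each tolerance: \(10^6\) replicate
pairs for the adjusted-\(R^2\) denominator identity (relative error
< 1%), \(10^4\) participants for marginal-calibration checks of the
generator, 200 cohorts of \(n = 450\) for bias-coefficient recovery
(within two Monte-Carlo SEs), and 300 cohorts × \(B = 500\) for the
size and power of the bootstrap comparison. Exact identities
(decomposition conservation, the \(\rho = 0\) reduction, OLS vs normal
equations) are checked at tolerances \(10^{-8}\)–\(10^{-12}\).

## Limitations

* The adjusted \(R^2\) inherits the classical-model assumption; if
  biomarker error correlates with traits in \(V\), the denominator no
  longer equals \(\mathrm{var}(Z)/\mathrm{var}(W)\).
* The Wald bootstrap p-value is anticonservative at the nested-model
  boundary (see above).
* Calibration equations are fit and reported; their downstream use in
  disease-association models (hazard ratios with calibrated intakes) is
  out of scope.
* With the study's own strata weights, small race categories make
  rank-deficient designs likely below roughly \(n = 150\); the generator
  is not intended for very small cohorts without re-weighting.
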