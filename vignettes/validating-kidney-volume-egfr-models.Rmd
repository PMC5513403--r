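---
title: "Validating and updating kidney-volume-based eGFR prediction models"
author: "adpkdval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating kidney-volume-based eGFR prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpkdval)
```

## The problem

In autosomal dominant polycystic kidney disease (ADPKD), cyst growth drives
kidney enlargement for decades before kidney function, measured as estimated
glomerular filtration rate (eGFR), begins to fall. A widely used risk tool
classifies patients into five ordinal subclasses, 1A through 1E, from a
single pair of measurements — age and height-adjusted total kidney volume
(HtTKV, ml/m) — and predicts future eGFR from baseline covariates with a
linear mixed model. Before such a model can guide treatment decisions (for
instance, selecting patients for tolvaptan), it must be shown to transport:
applied with its coefficients *frozen* to a cohort it has never seen, it
should remain calibrated and discriminating.

`adpkdval` implements that external-validation workflow end to end:

1. a seeded synthetic cohort generator emulating the longitudinal structure
   of a published ADPKD validation cohort;
2. risk subclassification and class-transition summaries;
3. the Mayo-form linear mixed eGFR model — representation, fitting,
   population-level prediction, and *partial updating* in which only the
   kidney-volume coefficient is re-estimated;
4. multiple imputation of missing follow-up HtTKV by a multivariate-normal
   data-augmentation sampler;
5. an agreement/discrimination metric suite (Bland-Altman bias and 95%
   limits of agreement, P30, two R² variants, AIC, CRPS) with patient-level
   k-fold cross-validation;
6. a pipeline that assembles everything into a report table with one row
   per model.

## Risk subclassification

The implied yearly growth rate of a kidney observed at HtTKV $h$ and age $a$
is the constant rate that would carry a theoretical at-birth volume
$h_0$ (default 150 ml/m, exposed as a parameter) to $h$ by age $a$:

$$ r(h, a) = \left( \frac{h}{h_0} \right)^{1/a} - 1. $$

Classes are half-open rate intervals with boundaries at 1.5, 3.0, 4.5 and
6.0 %/yr; a boundary value belongs to the upper class (exactly 1.5 %/yr is
1B). `class_boundary_httkv()` inverts $r$ to draw the age-dependent HtTKV
limits between classes. Class transitions over follow-up compare the
baseline class with the class implied by the *last non-missing* follow-up
HtTKV at the age attained at that visit; patients with no usable follow-up
volume are excluded from the denominator.

A consequence of this algebra worth noting: a kidney that stops growing
*regresses* through the classes, because a constant volume at an older age
implies a smaller lifetime-average rate. The class is stationary only when
the kidney keeps growing at exactly its baseline-implied rate.

## The eGFR model

For patient $i$ at $t$ years of follow-up,

$$ \mathrm{eGFR}_{it} = x_{it}^\top \beta + b_i t + \varepsilon_{it}, \qquad
   b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{it} \sim N(0, \sigma^2), $$

where $x_{it}$ contains an intercept, $\log_2$ HtTKV at baseline (or
indicators for classes 1B-1E with 1A as reference), baseline age (years,
uncentred), sex (female = 1, male = 0), baseline eGFR from the CKD-EPI 2009
creatinine equation, linear time, and the interaction of time with every
baseline predictor. The random effect is a subject-specific *slope* on
years of follow-up; there is no random intercept by default (a correlated
random-intercept variant sits behind a flag for sensitivity analysis).
Population-level predictions set $b_i$ to its zero mean and carry the
marginal predictive standard deviation
$\sqrt{t^2 \hat\sigma_b^2 + \hat\sigma^2}$, which is what the CRPS uses.
A conditional (residual-only) interpretation would shrink the predictive
spread; the marginal choice is the honest one for a new patient whose slope
is unknown.

Fitting uses `lme4::lmer()`. Maximum likelihood is the default because AIC
comparisons across fixed-effect structures are only meaningful under ML;
REML is available by flag. The package also carries its own closed-form
marginal log-likelihood (the random slope integrates out to a rank-one
covariance per patient), used to score *frozen* coefficient sets on new
data — a frozen model has no fit object to ask for a likelihood — and as an
independent oracle in the tests.

### Partial updating

External validation freezes every coefficient. The update step re-estimates
*only* the HtTKV coefficient (optionally also its time interaction) against
the validation sample, holding everything else — including the intercept —
at the external values. Implementation: the frozen part of the linear
predictor becomes an offset, and a mixed model with the single refit term
(plus the random slope) is maximised. Variance components are always
re-estimated; only regression coefficients are frozen. Returned objects
carry the frozen coefficients bit-for-bit unchanged.

Two update designs are provided:

* **Model 1 (second volume).** Each patient's second HtTKV measurement
  (the earliest follow-up visit with a non-missing value, typically 6-12
  months after baseline) enters as an *additional* $\log_2$ term with a
  freshly estimated coefficient, the baseline terms staying frozen. Whether
  the second measurement should add to or replace the baseline one is
  genuinely open; the additional-term reading preserves the frozen model
  intact and is the default, with `replace_baseline = TRUE` as the variant.
* **Model 2 (time-varying volume).** The model's HtTKV covariate is
  redefined as the $\log_2$ HtTKV observed at each visit, everywhere it
  appears, and its main coefficient is refit. Without the interaction flag
  the frozen time-interaction coefficient simply applies to the redefined
  covariate; with it, the interaction coefficient is refit too. This keeps
  the fitted model and its predictions coherent — the alternative (mixing a
  time-varying main term with a baseline-anchored interaction) would make
  predictions depend on a covariate the refit never saw.

Updated models are evaluated by patient-level k-fold cross-validation
(default $k = 5$): folds partition patients, never visits, so no patient
informs a prediction of their own future. Metrics are pooled over all
held-out predictions; AIC, which is not a cross-validated quantity, comes
from the full-data update.

## Missing kidney volumes

Follow-up HtTKV is missing for a few percent of visits. Imputation assumes
a joint multivariate normal over per-visit
$(\log_2 \mathrm{HtTKV},\ t,\ \mathrm{age}_0,\ \mathrm{sex},\
\mathrm{eGFR}_{obs},\ \mathrm{eGFR}_0)$ and runs a data-augmentation
Gibbs sampler: a normal-inverse-Wishart draw of $(\mu, \Sigma)$ under the
Jeffreys prior given the completed data, then a conditional-normal draw of
each missing value given the observed variables in its row. Choices:

* imputation on the $\log_2$ scale — the model's own scale, where normality
  is most plausible, and back-transformation guarantees positive volumes;
* the outcome (observed eGFR) is *included* in the imputation model, as
  standard MI practice requires for congeniality;
* burn-in 500 iterations and thinning interval 100 between the $m = 30$
  saved data sets (both exposed); with one scalar missing per affected row
  the chain mixes almost immediately, so these defaults are generous;
* only follow-up HtTKV may be missing — any other missingness pattern is
  refused rather than silently mishandled.

Scalar performance metrics are pooled across imputations by their mean;
coefficient sets by Rubin's rules (between-imputation variance
$B = \sum_i (\beta_i - \bar\beta)^2 / (m-1)$, total
$W + (1 + 1/m)B$). Whether one should pool predictions, coefficients or
metrics is itself underdetermined; all three objects are available, with
the metric mean as the default report entry.

## The metric suite

* **Bias** = mean(observed − predicted); **95% limits of agreement** =
  bias ± 1.96 × SD of the differences ($n-1$ denominator; 1.96 literally,
  not a t-quantile). The identity between the three reported numbers is
  exact in every emitted report.
* **P30** = percentage of predictions within 30% of the observed value,
  boundary inclusive.
* **R²** in two variants: $1 - \mathrm{SSE}/\mathrm{SST}$ (penalises
  miscalibration, can be negative) and squared Pearson correlation (blind
  to calibration). They coincide for unbiased linear predictions and
  published "R-squared" values do not always say which was meant, so
  reports always carry both; the headline column is configurable.
* **AIC** = $-2\ell + 2k$ with $k$ counting fixed effects plus variance
  components under ML.
* **CRPS** for a normal forecast in closed form,
  $\sigma[z(2\Phi(z)-1) + 2\phi(z) - 1/\sqrt{\pi}]$ with
  $z = (y-\mu)/\sigma$, degenerating to $|y - \mu|$ at $\sigma = 0$; the
  empirical (sample) CRPS, computed by the $O(n \log n)$ sorted-sample
  identity, serves as its Monte-Carlo oracle. The frozen risk-class model
  row reports no CRPS: that model was applied with published coefficients
  only, and no predictive-distribution convention for it is established.

## What the synthetic generator emulates — and what it does not

The generator is the package's study-conditions module, not a test dial.
Defaults emulate the published structure of a Swiss ADPKD validation
sample: n = 214; baseline age median 34 (IQR 27-40) years and eGFR median
82 (IQR 70-95) ml/min/1.73m² drawn by piecewise-linear quantile
interpolation through the published min/quartile/max (this hits the
published median and IQR by construction, which uniform-plus-rejection
sampling only approximates); HtTKV log-normal with median 497 ml/m and
sdlog 0.65 (IQR ≈ 319-774 against the published 317-762); 44% female;
heights normal by sex (1.66/1.78 m); a second visit uniform within 6-12
months of baseline, then annual visits with ±0.15 y jitter; per-patient
follow-up uniform on 0.42-10.28 y; 3% MCAR missingness in follow-up HtTKV.
A development-sample counterpart (`mayo_generator_config()`) points the
same machinery at the published development-cohort structure (n = 376, age
44, eGFR 71, HtTKV 651, follow-up 1-11 y).

Kidney growth is exponential, $h(t) = h_0 (1+r)^t$, with the per-patient
true rate drawn as a log-normal multiplier (median 2.0, sdlog 0.25) on the
baseline-implied class-typical rate. The multiplier above one makes current
growth outpace the lifetime average — the signature of a young cohort — and
reproduces the published transition asymmetry (progression dominating
regression by roughly an order of magnitude) together with the 8%
multiplicative measurement noise typical of repeated volumetry.

Observed eGFR comes from the generating truth's fixed effects plus the
subject-specific slope and residual noise (SD 2 and 5 ml/min/1.73m²
respectively). Follow-up ends after the first visit with observed eGFR
below 15 ml/min/1.73m², emulating progression to advanced CKD ending study
participation; because that dropout is triggered by an *observed* value it
is missing-at-random, and likelihood-based fits remain unbiased (a fact the
test suite exploits: a working-independence OLS fit on the same cohorts is
visibly biased, the mixed-model ML fit is not). Serum creatinine is
back-derived from baseline eGFR through the inverse CKD-EPI equation and is
synthetic-only.

The validation cohort's generating truth deliberately shifts the
$\log_2$ HtTKV coefficients relative to the development truth (−2.5 → −3.0
main, −0.35 → −0.40 interaction). This emulates a kidney-volume term
mis-calibrated between settings — as arises when development and validation
cohorts measure TKV by different methods — and is what gives partial
updating something real to correct; with identical truths, updating could
only ever add noise.

What the generator does *not* emulate: measurement error in creatinine and
height; genotype (PKD1/PKD2) effects; nonlinear eGFR trajectories;
informative visit timing; atypical (Class 2) morphology; death or dialysis
as events. Passing tests therefore show that the pipeline's statistical
machinery is correct under the stated generative model — they do not show
that the clinical model is correct in real patients.

## Numerical choices and degenerate inputs

* One master seed per run; every sub-stream (cohorts, missingness,
  imputation, folds) derives from it deterministically, so a fixed
  configuration reproduces its report bundle byte for byte.
* CKD-EPI constants (κ = 0.7/0.9, α = −0.329/−0.411, exponent −1.209,
  0.993 age term, 1.018 female factor) are embedded explicitly; the race
  coefficient is omitted as underivable from the available fields and
  irrelevant to the mechanisms under test.
* `n_patients = 0` yields an empty cohort, not an error; empty transition
  summaries report percentages as `NA`.
* Singular fixed-effect designs (e.g. a single-sex cohort) are refused with
  the aliased terms named.
* The sample CRPS uses the sorted-sample identity
  $\frac{1}{n}\sum_i |x_i - y| - \frac{1}{n^2}\sum_i (2i - n - 1) x_{(i)}$,
  averaging over all $n^2$ ordered pairs (self-pairs included) to match the
  enumerable small-sample definition exactly.
* Observed eGFR is floored at 0.5 ml/min/1.73m² as a positivity guard; with
  the MAR dropout rule in place this touches at most ~1 visit in 2500.
* Mixed-model convergence is left to `lme4`'s defaults with derivative
  checks disabled for speed; the offset-equivalence test pins the update
  against an independent profiled-GLS optimiser at 10⁻⁶.

## Problem sizes

The test suite validates parameter recovery at n = 500 patients × 20
replicate seeds (joint zero-bias via Hotelling's T², variance components
within 20%), imputation mask-and-recover at n = 150 × 20 seeds × m = 30,
the CRPS closed form against 10⁶ stratified draws on a 5×5×5 grid, and the
updating-improves-CRPS ordering over 20 replicate develop/validate pairs at
the study's own sizes (376/214). The acceptance script runs one full study
at those sizes with m = 30 imputations and 5-fold cross-validation. These
sizes give Monte-Carlo error comfortably below every asserted tolerance
while keeping a complete run in the order of a minute.

## Known limitations

* The imputation model is joint-normal over a set that includes a binary
  sex indicator; this is the standard MVN-MI compromise and matters little
  with a single scalar imputed per row, but it is a model, not the truth.
* Partial updating assumes the continuous-HtTKV mode; the risk-class model
  has no single "kidney-volume coefficient" to refit, and attempts are
  refused rather than reinterpreted.
* The marginal CRPS treats the predictive distribution as normal with the
  model's own variance components; heavy-tailed prediction errors would be
  scored optimistically.
* Cross-validated metrics and the full-data AIC in the same report row come
  from different fits; they answer different questions (transportability vs
  in-sample parsimony) and should not be compared against each other.

## A minimal session

```{r example, eval = FALSE}
cohort <- generate_cohort(generator_config(n_patients = 214, seed = 1))
dev <- generate_cohort(mayo_generator_config(seed = 2))
frozen <- fit_development_model(dev, mode = "continuous_httkv")

pred <- predict_cohort(frozen, cohort)
validation_report(pred$egfr_obs, pred$egfr_pred, pred_sd = pred$pred_sd,
                  loglik = marginal_loglik(frozen, cohort),
                  n_params = length(frozen$beta) + 2)

updated <- partial_update(frozen, cohort, "model2_time_varying")
cross_validated_report(cohort, frozen, "model2_time_varying", k = 5, seed = 3)

bundle <- run_study(pipeline_config(master_seed = 1, output_dir = "results"))
bundle$table2
```
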