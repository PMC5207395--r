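---
title: "Normative modelling of brain aging: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of brain aging: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `normbrain`, the
assumptions it rests on, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. The model

### Cohort definition

The normative ("null") model must be fitted on subjects who are healthy by
a criterion *stronger* than the clinical diagnosis, because cognitively
normal elderly people can already carry amyloid/tau pathology. Two labels
are derived per subject from their visit history:

* `dx_last` — the longitudinal diagnosis class: `sHC` (normal at every
  visit), `sMCI`, `cMCI`, `sAD`, `cAD` (reached dementia after a normal or
  MCI start). A sequence that reverts after dementia is flagged with a
  warning but still classified by the presence of dementia, since the
  classes are defined by conversion events rather than terminal state.
* `csf_profile` — *normal* iff **every** available CSF observation satisfies
  Aβ₁₋₄₂ ≥ 192 pg/mL **and** τ ≤ 93 pg/mL (both cut-offs inclusive, read
  literally from their published form). One violating visit makes the
  subject abnormal. The cut-offs come from autopsy-validated thresholds and
  are configuration values, not constants in code.

Subjects with `dx_last = sHC` and a normal profile form the null cohort;
all others form the early-prediction cohort. The split is a partition: the
two sets are disjoint and exhaust the input.

### Per-ROI mixed model

Each regional biomarker (ROI) is standardized to zero mean and unit
variance over the pooled null-cohort observations — new cohorts are always
standardized with these same null parameters — and fitted with a
random-intercept linear mixed model (REML, `lme4`):

$$y_{ijr} = \beta_1^r + \beta_a^r\,\mathrm{age}_{ij} +
\beta_e^r\,\mathrm{educ}_i + v_{ir} + \epsilon_{ijr},\qquad
v_{ir}\sim N(0,\psi),\ \epsilon_{ijr}\sim N(0,\sigma^2).$$

Assumptions: a common annual rate of change per ROI across healthy
subjects (random intercepts, fixed slope); homoscedastic, within-subject
independent errors (the error covariance is $\sigma^2 I$ — the minimal
structure consistent with a random-intercept model); education as a linear,
time-invariant covariate. Unbalanced visit counts and monotone dropout are
handled by the likelihood. Age enters **in raw years, uncentered**, so that
the model intercept is literally the extrapolation to age 0 and the
subject-specific baseline $y_{0,ir} = \beta_1^r + v_{ir}$ (fixed intercept
plus conditional random-effect mode) has the interpretation the downstream
arithmetic requires. The price is that $y_0$ absorbs roughly
$75\times$ the slope estimation error; consumers of the intercept table
should expect per-ROI offsets of that order (they cancel in the residuals,
which is what the pipeline actually uses).

The p-value for $\beta_a$ is a two-sided Wald z-test. With the default
study sizes the age effect draws most of its information from the
within-subject visits (effective df in the hundreds), where the z and
Satterthwaite-t references agree; simulations during development confirmed
nominal type-I error for the Wald test under independent-ROI conditions, so
the simpler test is kept.

### Variant / quasi-variant classification

A ROI is *variant* (`vr`) if $|\beta_a| > 0.01$ SD/year **and** $p \le
0.05$; *quasi-variant* (`qvr`) if $|\beta_a| \le 0.01$. Because ROIs are
standardized to unit variance, the threshold is exactly "1% of the ROI's
standard deviation per year". The rule as published is not exhaustive: a
large but non-significant annual change satisfies neither definition. Such
ROIs are labelled `excluded` and dropped from both intercept transfer and
features — exclusion is explicit and logged rather than silently absorbed
into either class.

### Intercept transfer (kernel PLSR)

The method's key identification assumption is that quasi-variant regions
are essentially untouched by both aging and (by construction of the
feature set) disease, while variant-region baselines cannot be observed
directly in elderly subjects. The null cohort provides both intercept sets,
so a multivariate linear map can be learned and applied to new subjects.

Partial least squares regression fits this situation: many collinear, noisy
predictors (the qvr intercepts share latent subject-level structure) and
multiple responses modelled jointly. The kernel algorithm is implemented
in-package (weights from the dominant singular vector of $X^\top Y$, score
deflation, coefficients $B_a = W_a (P_a^\top W_a)^{-1} Q_a^\top$) and is
validated in the test suite against an independently written brute-force
NIPALS implementation. The number of components minimizes the
leave-one-out root-mean-squared prediction error pooled over **all**
variant responses — a single component count for the whole map, matching
the single-model formulation; per-response selection was the open
alternative and was rejected to keep one transfer model per gender.

For a **new** subject the qvr intercepts are not part of any fit. They are
estimated by inverting the expected-value relation at each observation,
$y_0 = y_{ij} - \beta_a\,\mathrm{age}_{ij} - \beta_e\,\mathrm{educ}_i$, and
averaging over the subject's visits. This estimator is exact for noise-free
data, unbiased under the null model, and uses all visits (a single-visit
variant would only add noise). This step is an interpretation: the source
framework does not specify how new-subject qvr baselines are obtained.
Missing predictor *cells* are imputed with the transfer model's stored
predictor means — neutral under centring (note the standardized-scale mean
intercept is not 0, because the intercept absorbs $-\beta_a \times$ mean
age; the model's own centring vector is the correct neutral value).

### Residuals, features, classifiers

Expected values $\hat y_{ijr} = y_{0,ir} + \beta_a^r\,\mathrm{age}_{ij} +
\beta_e^r\,\mathrm{educ}_i$ give residuals $e_{ijr} = y_{ijr} - \hat
y_{ijr}$, one row per observation (subjects contribute multiple rows — the
evaluation accounts for that, below). Retained columns ($E_v$): every
variant column, plus quasi-variant columns not identically zero. The
retention rule is ambiguous in its source ("either the vr ROIs or the qvr
ROIs whose residuals are different from zero"); it is resolved as
*vr-always-in, qvr-if-nonzero* because variant residuals are the method's
signal, while quasi-variant residuals vanish identically for single-visit
subjects under the mean-inversion rule. The test suite verifies that
dropping all-zero columns cannot change any classifier's input.

Feature sets: **F1** = $E_v$ + age; **F2** = F1 + MMSE + CDR global. Labels
are the coarse class (HC/MCI/AD) of either the visit diagnosis
(`current`) or the final longitudinal class (`last`; every visit of a
converter carries the future outcome, so the classifier learns to predict
it from the present state).

The SVM uses a Gaussian radial kernel with cost $C = 1$. The kernel width
is not specified by the protocol; the default is the standard heuristic
$\gamma = 1/(p \cdot \mathrm{Var}(X_\text{train}))$, logged in each report
and configurable. Feature scaling uses training-split statistics only.
Evaluation uses 10 repeated random subject-stratified 60/40 splits: the
published protocol describes both "ten-fold cross validation" and 60/40
train/test fractions, which are mutually inconsistent; the split-size
statement is the operational one and is implemented, with "ten" retained as
the number of repeats. Sensitivity treats the disease class of each pair as
positive (unstated in the protocol; documented here). A class with fewer
than 5 subjects skips the experiment with a warning rather than producing a
meaningless split.

### Advancement

For each converter whose visit diagnosis differs from their final class at
some visits, the clinical conversion age is the first visit where the visit
diagnosis reaches the final class. If, at an earlier visit (diagnosis still
pre-conversion), the early-prediction classifier already output the final
class, the subject's advancement is the difference of those two ages,
averaged over the repeats in which the subject was tested. Only the
quantity's name and example magnitudes are given in the source; this
formalization — earliest *correct* pre-conversion prediction, subject-level
averaging, gender × five-year stratification by age at conversion — is the
package's own. Subjects never correctly predicted before conversion
contribute nothing (they are not counted as zero).

## 2. Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `abeta_cutoff`, `tau_cutoff` | 192, 93 | pg/mL | autopsy-validated CSF thresholds |
| `vr_threshold` | 0.01 | SD/year | the 1%-of-SD annual-change rule |
| `alpha` | 0.05 | — | significance for the age effect |
| `max_components` | 10 | — | LOO search bound for the PLSR |
| `svm_cost` | 1 | — | published SVM configuration |
| `svm_gamma` | `1/(p·Var(X))` | — | standard width heuristic; logged |
| `train_fraction`, `n_repeats` | 0.6, 10 | — | subject-grouped evaluation |

## 3. The synthetic cohort generator

The generator exists so that every stage is testable against ground truth
without restricted clinical data. It reproduces the structural features the
pipeline relies on:

* visit schedule 0, 6, 12, 18, 24, 36, 48, 60 months, monotone dropout
  (8%/visit by default);
* baseline age uniform on [60, 90) so all five-year strata are populated;
  education uniform on 12–20 years;
* per-ROI lines $y = y_0 + \beta_a\,\mathrm{age} + \beta_e\,\mathrm{educ} +
  \epsilon$ generated directly on the standardized scale, variant slopes
  0.02–0.08 SD/yr in magnitude (80% negative — atrophy dominates, with some
  expanding regions such as ventricles), quasi-variant slopes within
  ±0.005 SD/yr, so the ground-truth labels are unambiguous around the 0.01
  boundary;
* subject intercepts $y_0 = Lf + \text{noise}$ from `latent_dim = 3` shared
  factors (total latent SD 0.5, ROI-specific noise SD 0.1), so an exact
  linear qvr→vr intercept map exists and is exported as ground truth;
* observation noise SD 0.2 — together these give intercept variance ≈ 0.26
  and residual variance 0.04, i.e. strong individual-level effects, which
  is the regime that motivates random intercepts;
* disease effects **confined to a subset (60%) of variant ROIs**: an
  intercept drop of `disease_offset` (1.0 SD, the order of hippocampal
  atrophy in dementia) scaled by the biomarker state (normal 0, MCI ½,
  dementia 1) plus `disease_slope_accel` (0.15 SD/yr) accruing from
  dementia onset — so a converter's post-conversion residual in an affected
  region is $-(\text{offset} + \text{accel}\cdot\Delta t)$ in expectation;
* conversion visits uniform over the realized non-baseline visits (the
  least-informative choice — conversion timing is not modelled in the
  source); an optional `biomarker_lead_visits` makes the biomarker state
  change *k* visits before the clinical label, which is how the advancement
  metric is validated against a known lead;
* CSF at baseline only (longitudinal CSF is typically unavailable), from
  per-group two-component mixtures — bimodal Aβ, unimodal normal τ in
  controls — with abnormality probabilities 0.08/0.65/0.50/0.90/0.85 for
  sHC/sMCI/cMCI/sAD/cAD, so ≥90% of stable controls pass the normal-CSF
  rule while impaired groups are CSF-heterogeneous;
* MMSE and CDR-global drawn from clinical-state-dependent ranges
  (informative, as the real scores are), which is what makes F2 at least as
  good as F1 on synthetic data.

What it does **not** emulate: real anatomy or inter-ROI correlation beyond
the latent intercept factors; measurement batch effects; non-linear aging;
diagnosis noise; informative (disease-dependent) dropout; longitudinal CSF.
Passing tests therefore demonstrate the pipeline's correctness and internal
calibration, not clinical performance: synthetic separability is higher
than real-data separability (subject-classification accuracies near 100%
here vs ~80–94% on clinical data), because the generator's disease signal
is exactly the structure the residual method is built to detect.

## 4. Numerical choices and degenerate inputs

* Constant ROIs are dropped at standardization with a warning (never NaN).
* ROIs observed at fewer than two distinct time points are skipped before
  fitting.
* Noise-free input makes the mixed model's profiled likelihood ill-defined
  (residual variance exactly 0); `fit_lme()` detects this (saturated-model
  residual variance < 1e−18) and returns the exact least-squares solution,
  flagged `degenerate`, with the education effect identified by the
  between-subject regression — the REML limit. This keeps the algebraic
  identity tests exact.
* Singular ψ→0 fits are valid and noted (`singular`); non-converged fits
  are flagged and excluded from vr/qvr classification.
* PLSR component extraction stops when the deflated cross-product matrix or
  a score's variance falls below 1e−12; E_v's "different from zero" uses
  tolerance 1e−12.
* Ties in a subject's majority class during split stratification go to the
  first label encountered; splits, the generator, and the SVM repeats are
  all seeded, and the pipeline is bit-reproducible given its seeds.

## 5. Problem sizes used in the checks

The test suite validates estimator calibration with 200 simulated ROIs
(40 subjects × 8 visits) for slope bias and Wald-interval coverage, and
1000 zero-slope ROIs for the type-I error of the variant test — in the
latter, subject intercepts are dominated by ROI-specific noise
(`intercept_sd = 0.1`, `intercept_noise_sd = 0.5`) so the 1000 replicate
tests are nearly independent; with shared latent factors the test
statistics would be strongly correlated across ROIs and the empirical
rejection rate would not concentrate at the nominal level. Rule-recovery
checks use 30+30 ROIs with separated slope regimes (quasi-variant
magnitudes ≤ 0.002 SD/yr, observation noise 0.1), chosen by power analysis
so that per-ROI misclassification under the 0.01 threshold is well below
1%. End-to-end checks run the default 250-subject cohort; the acceptance
script does the same and completes in seconds.

## 6. Known limitations

* Random slopes are deliberately out of scope: the model assumes a common
  healthy rate of change per ROI, so true slope heterogeneity inflates σ².
* The age-0 extrapolation makes intercept *levels* sensitive to slope
  error; all downstream quantities use differences in which this cancels,
  but the intercept table itself should not be over-interpreted.
* The advancement metric conditions on an eventually-correct prediction, so
  even an uninformative classifier produces a positive value when it
  guesses right early; it is meaningful relative to a known lead (as
  validated with the generator) or between methods, not in absolute terms.
* With the default CSF mixtures most stable controls enter the null cohort,
  leaving few hold-out HC subjects per gender; early-prediction experiments
  needing an HC class may be skipped at small cohort sizes (a warning is
  issued). Subject classification, which labels by visit diagnosis, is
  unaffected.
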