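---
title: "Methods: OGTT indices, insulin-resistance classification and anthropometric equivalence cut-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OGTT indices, insulin-resistance classification and anthropometric equivalence cut-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isiequiv)
```

## The problem

Standard obesity thresholds — BMI 25 and 30 kg/m², waist circumference
94 cm in men and 80 cm in women — were derived largely in populations of
European ancestry. In populations with a different fat distribution the
same anthropometric value can correspond to a substantially worse
metabolic state, so applying the standard thresholds under-detects
insulin resistance and diabetes risk. `isiequiv` implements the analysis
chain needed to quantify this in a two-population OGTT cohort: it computes
OGTT-derived indices of insulin sensitivity and beta-cell function,
classifies insulin resistance against the reference population's index
tertiles, and — its core — derives, per sex, the *equivalence cut-off*:
the BMI or waist value at which the comparison population has the same
age-adjusted insulin sensitivity as the reference population at a
standard threshold.

## OGTT indices

From a 75-g OGTT with samples at 0, 30, 60, 90 and 120 minutes
(`ogtt_indices()`):

* **Mean glucose / mean insulin** — unweighted arithmetic mean of the
  0/30/60/120-minute values. The 90-minute sample is deliberately
  ignored everywhere, and the package generates it in synthetic data so
  that this rule is actually exercised.
* **Matsuda insulin sensitivity index**
  $ISI = 10000/\sqrt{G_0 I_0 \bar G \bar I}$ with glucose in mmol/L and
  insulin in mIE/L. The original composite index is defined on mg/dL
  glucose; keeping mmol/L (with the same constant 10000) rescales the
  index by ≈ 18× and puts typical population medians in the 70–130
  range, the scale on which the tertile boundaries below live. A
  `glucose_units = "mg/dL"` option converts (1 mmol/L = 18.0182 mg/dL)
  for data recorded in the other convention.
* **Corrected insulin response**
  $CIR = 100\,I_{30}/\big(G_{30}(G_{30}-3.89)\big)$, the common mmol/L
  variant (3.89 mmol/L = 70 mg/dL); the offset is configurable because
  several published variants exist. When $G_{30} \le 3.89$ the index is
  undefined: the subject is flagged (`cir_undefined`) and excluded from
  DIo analyses rather than given a negative response.
* **Oral disposition index** $DI_o = CIR \times ISI$, exactly; the
  identity is maintained to full double precision and tested on every
  generated subject.

Missingness is complete-case *per derived quantity*: a subject missing
one sample loses exactly the indices that depend on it, and never
affects other subjects.

## Classification

`exclude_diabetes()` removes subjects with fasting glucose ≥ 7.0 mmol/L
(or a diabetes-medication flag when the column exists) before any
analysis. `tertile_reference()` splits the *reference group's* ISI into
three equally large classes — insulin resistant, intermediate, insulin
sensitive — using the interpolating type-7 quantile rule (positions
$p(n-1)+1$; a nearest-rank option exists because the choice is not
identified by reported boundaries alone). Classification boundaries are
deliberately asymmetric: resistant is strict (`ISI < cut_lo`), the upper
classes are weak (`≥`), and ties are assigned by these inequalities,
never split. `prevalence_crosstab()` produces the group × sex ×
adiposity cross-tabulations with half-up percentages at one decimal, the
usual reporting style.

## The equivalence cut-off model

`cutoff_model()` is the package's central estimator. For each sex and
outcome (log10 ISI or log10 DIo):

1. **Age adjustment** (`age_adjust_outcome()`): log10 values are
   residualized on age by least squares, pooled across groups within
   sex, and the pooled mean is added back. Adjusted values are exactly
   uncorrelated with age and preserve the pooled mean. Pooling uses one
   age slope per sex, so the adjustment shifts both groups coherently
   and cancels from any between-group comparison at a common age; a
   `per_group_adjust` switch fits separate slopes instead, since either
   choice is defensible and they differ only when the groups' age
   effects truly differ.
2. **Group lines** (`fit_group_line()`): ordinary least squares of the
   adjusted outcome on BMI or waist within each group. A straight line
   is the minimal functional form consistent with the single-crossing
   logic of "the same level at an equivalent measure value"; anything
   more flexible can cross more than once and leaves the cut-off
   ill-defined.
3. **Solving** (`equivalence_cutoff()`): with reference line
   $(a_r, b_r)$ and comparison line $(a_c, b_c)$, the level at the
   reference threshold $x_r$ is matched at
   $x_c = (a_r + b_r x_r - a_c)/b_c$. Cut-offs are reported raw and
   snapped to a reporting grid (0.5 kg/m² for BMI, 1 cm for waist,
   half-up). A comparison slope below $10^{-8}$ in magnitude is
   declared non-identifiable; a solution outside the comparison group's
   observed measure range is flagged as an extrapolation (flagged, not
   forbidden — the quantity is still the line intersection).

Uncertainty comes from a subject-level percentile bootstrap, resampling
with replacement within group × sex and re-running the adjustment,
fits and solver on each resample (1000 resamples in the pipeline
configuration; a seed is mandatory). Strata below `min_n = 30` subjects
are marked unreliable.

The invariances that make the construction trustworthy are tested
directly: the comparison line evaluated at the returned cut-off
reproduces the reference level to 1e-10; adding a constant to every
subject's log10 outcome moves both lines but no cut-off; a group
compared with itself returns the thresholds exactly.

## Risk-factor regression

`isi_regression()` fits log10 ISI on a declared term list by OLS.
Continuous predictors are divided by their sample SD (n−1 denominator,
no centering) so coefficients are per 1 SD; binary indicators stay on
their natural scale. Confidence intervals use the normal approximation
(appropriate at the cohort sizes involved; t-based by option), the
significance threshold is two-sided 0.05 throughout, and an optional
backward-elimination mode drops terms with p ≥ 0.05 one at a time to
emulate stratified published tables whose exact model path is unknown.
Multicollinearity is screened with variance inflation factors
($VIF_j = 1/(1-R_j^2)$), warning at the customary acceptance bound 3.5.

`interaction_scan()` implements gated interaction testing: to limit the
multiple-testing burden, a term × moderator product is tested only when
the term's marginal effect is significant; all other terms are reported
as skipped. Calibration is verified by simulation: type-I error within
[3%, 7%] at α = 0.05 (500 null replicates at n = 800) and ≥ 80% power
for a standardized interaction of 0.1 at n = 1500, with the moderator
effect-coded (±1) so that the product term has unit variance and 0.1 is
a standardized coefficient.

`age_adjusted_comparison()` reproduces the descriptive-table machinery:
group differences in means by linear regression on group + age, and in
proportions by logistic regression (IRLS, deviance tolerance 1e-8, at
most 50 iterations), with complete separation diagnosed from fitted
probabilities at the 0/1 boundary.

## The synthetic cohort generator

No subject-level data accompany the study this package operationalizes,
so `generate_cohort()` provides cohorts carrying exactly the structure
the estimators assume:

* per stratum (group × sex): truncated-normal age (30–75 y, rejection
  sampling) and BMI; waist linear in BMI (correlation 0.85) with
  Gaussian residual;
* a latent $\log_{10} ISI = a + b_{BMI}(BMI-25) + b_{age}(age-50) +
  \varepsilon$, with log-normal noise (σ = 0.2 on the log10 scale) —
  the log-normal choice matches the log10 transforms used throughout;
  a latent DIo with the same linear structure (σ = 0.3);
* a glucose trajectory from a stratum template with multiplicative
  log-normal noise (σ_log = 0.10, which also yields a realistic ~1%
  exclusion rate at the 7.0 mmol/L fasting bound);
* an insulin trajectory obtained by *exact inversion*: the 30-minute
  insulin is set from the planted CIR, and the remaining profile
  $(I_0, I_{60}, I_{120}) = (s, 4s, 3s)$ has its scale $s$ solved from a
  quadratic so the Matsuda formula applied to the generated samples
  reproduces the latent ISI exactly. Recomputed ISI and CIR therefore
  equal their planted values to machine precision — with noise on, not
  only in the zero-noise limit — so parameter-recovery tests measure the
  estimators, not the generator. The fixed response shape is a plausible
  OGTT profile; only its scale carries information.
* covariates linked to the latent sensitivity: triglycerides load
  negatively and HDL positively on log10 ISI; smoking and
  family-history prevalences and physical-activity distributions are
  stratum constants.

Three scenarios (`default_params()`):

* **`study_like`** — stratum sizes (326/493/362/683), age, BMI and waist
  moments, ISI and DIo medians, glucose levels and covariate prevalences
  follow the published two-population cohort description. The BMI slopes
  of the latent ISI lines (−0.0247 to −0.0280 per kg/m²) are the
  published stratified per-SD waist coefficients rescaled to the BMI
  scale, which reproduces both the distinct slopes by group and sex and,
  downstream, equivalence cut-offs and tertile boundaries close to the
  published ones.
* **`null`** — both groups drawn from the reference distribution;
  exchangeable by construction. Cut-offs must recover the thresholds.
* **`planted_shift`** — the comparison line is the reference line
  displaced horizontally by Δ kg/m², so the true BMI cut-off at any
  threshold $x$ is exactly $x-\Delta$. The validation scenarios plant
  the *unconditional* adiposity–sensitivity coupling (−0.055 per kg/m²,
  steeper than the covariate-adjusted slopes behind `study_like`,
  intercepts recomputed to keep the medians): recovery of a planted
  shift to ±0.2 kg/m² at 2000 subjects per group requires the slope
  signal this coupling provides, and a horizontal-shift truth is only
  meaningful relative to a declared slope.

What the generator does **not** emulate: physiological OGTT dynamics
(no minimal model; the insulin shape is fixed), assay error, shared
noise between ISI and DIo, non-linearity or heteroscedasticity of the
adiposity–sensitivity relation, and sampling/participation structure.
Passing recovery tests therefore demonstrate the estimators are correct
under the stated linear model — they do not validate linearity in any
real cohort.

## Numerical choices and degenerate inputs

* Tertile quantiles: interpolating type-7 positions; a reference sample
  of size 3k with distinct values splits exactly k/k/k.
* Half-up rounding (`round_half_up()`) for all reported percentages and
  grid-snapped cut-offs; base R's round-half-to-even would differ at
  exact halves.
* Solver tolerance: comparison slopes with |b| < 1e-8 are
  non-identifiable; round-trip identities are maintained to 1e-10.
* Degenerate references (fewer than 3 finite ISI values, or all equal)
  and zero-variance measures are hard errors; zero age variance degrades
  to unadjusted log10 values with a warning.
* All index computations are pure doubles, seed-free; every stochastic
  stage (simulation, bootstrap) requires an explicit seed, and the
  pipeline derives per-stage sub-seeds from one master seed.

## Problem sizes used in the test suite

Simulation-backed checks run at: planted-shift recovery Δ ∈ {1, 2, 4}
over 20 seeds at 2000 subjects/group; bootstrap coverage at 200
resamples over 50 replicates (400 subjects/group, men); interaction
type-I error over 500 null replicates at n = 800 and power over 50
replicates at n = 1500; generator calibration at 1250 subjects/stratum.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping the default suite under a minute.

## Known limitations

* The equivalence construction is cross-sectional: it equates levels of
  an index, not prospective risk, and inherits every limitation of the
  Matsuda index as a surrogate for clamp-measured sensitivity.
* Linearity of adjusted log10 outcome in BMI/waist is assumed, not
  tested; with strongly non-linear relations the single-crossing logic
  breaks down (a local-regression diagnostic can be layered on the
  stored model data, but the reported cut-offs are always the linear
  ones).
* Which exact Matsuda variant, CIR offset, quantile rule and age
  adjustment (pooled vs per-group, centered or not) the original
  analysis used is not recoverable from the published description;
  each choice here is explicit and configurable, with the defaults
  stated above.
* Published multivariate coefficient tables cannot pin down univariate
  line geometry, so the `study_like` scenario reproduces the published
  cut-offs approximately (within a few percent), not exactly.
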