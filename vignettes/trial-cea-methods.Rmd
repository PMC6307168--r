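---
title: "Methods: trial-based cost-effectiveness analysis with multiple imputation and bootstrapped ICERs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the parameters that matter and their
defaults, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made. The setting is an economic
evaluation alongside a two-arm pragmatic randomised trial — a telephone
weight-management referral versus usual care for overweight patients with
knee osteoarthritis — with self-reported outcomes at weeks 0, 6 and 26 and
six-week-recall resource-use inventories at the two follow-ups.

## Effect endpoints

**QALYs.** Utility scores (a preference-based index in (0, 1], here derived
from SF-12 responses scored externally; the scoring tariff itself is out of
scope and utilities are accepted as input) are integrated over the 26-week
horizon by the trapezoidal rule and converted to years:

$$\mathrm{QALY} = \frac{1}{52}\sum_k \frac{(t_{k+1}-t_k)(u_k+u_{k+1})}{2}.$$

With the fixed week \{0, 6, 26\} grid this is
$(3(u_0+u_6) + 10(u_6+u_{26}))/52$. Exact week fractions (6/52, 20/52) are
used rather than calendar days; the instrument's measurement grid is weekly
and nothing finer is observed. QALYs are computed *after* imputation, by
integrating the imputed timepoint utilities, so the within-participant
correlation of the utility trajectory is preserved in the imputations. A
participant's QALY is missing whenever any timepoint utility is missing
pre-imputation; there is no silent zero-fill.

**Clinical endpoints.** Knee pain (11-point NRS), disability (WOMAC total,
0–96, a plain sum of 24 items with no prorating), self-reported weight, and
BMI (weight over baseline height squared — height is measured once). All are
analysed as week-26 values adjusted for their own baseline (ANCOVA-style)
rather than as change scores, which is the more efficient and less
baseline-imbalance-sensitive parameterisation.

## Costs

All costs are in 2016 Australian dollars; `cpi_adjust()` converts between
price years by CPI ratio. No discounting is applied anywhere — the horizon
is 26 weeks, under any convention too short to discount — and no discounting
parameter is exposed.

* **Intervention** (micro-costing): brief advice plus a per-coaching-call
  rate times calls received; control participants cost zero. The published
  analysis reports only the resulting mean ($622 per intervention
  participant at a mean of 4.7 calls), not the two components, so the
  defaults ($58 + $120/call) are calibrated to reproduce that mean and are
  configurable, not asserted.
* **Healthcare and medications**: inventory counts times unit costs keyed to
  published Australian tariffs (e.g. GP consult $37.05, hospital admission
  $4422.31). Where a tariff is a range (initial vs follow-up consult rates)
  and the inventory does not record visit order, the midpoint is used.
  Unknown resource labels are an error, never a silent zero — silent zeros
  would bias cost differences toward the null. Medication prices and the
  wage and CPI tables shipped in `default_unit_costs()` are synthetic
  defaults on the right scale, intended to be replaced by study-specific
  tables.
* **Absenteeism** (human capital approach): sickness-absence days × a
  standard workday × the age-band/gender-specific average hourly income.
  The workday defaults to 7.6 hours (the Australian full-time norm) because
  the source method multiplies days by an *hourly* income without stating
  hours per day; it is a configurable parameter.
* **Period interpolation**: each category is observed over two 6-week recall
  windows (weeks 0–6 and 20–26). Assuming linearity, the 26-week cost is the
  window average scaled by 26/6: `((c6 + c26)/2) * 26/6`. An alternative
  reading — fitting a per-participant linear trend through the two windows —
  differs only by a constant factor convention; the average-then-scale form
  is used throughout and is linear and symmetric in the two windows.

Perspectives differ only in the total: societal = intervention + healthcare
+ medication + absenteeism; healthcare excludes absenteeism. Category values
never change with perspective. Presenteeism is not costed (not collected).

## Missing data

Missing cost and effect measures are imputed by chained equations
(`mice_impute()`), m = 10 completed datasets, separately within each arm so
an arm's imputations depend only on that arm's rows. Imputation operates at
the *cost-category window* level (healthcare/medication/absenteeism cost per
recall window), not the resource-item level: items within a window are
missing jointly (whole questionnaires go unreturned), and category-level
imputation keeps the conditional models tractable at n = 119.

Conditional models: predictive mean matching for continuous targets —
ridge-stabilised Bayesian regression draw, donors the k = 5 observed cases
nearest in predicted value — which respects the right skew and point masses
of cost data because imputed values are always observed donor values;
logistic draws for binary targets. Ten chained iterations per dataset.
Predictors are the fully observed baseline covariates related to
missingness and outcome (education, employment, Indigenous status, age,
country of origin, gender, pain duration, waiting-list days) plus the
baseline outcome values. Each target's model also includes a small set of
auxiliary targets — the same measure at the other timepoint and its closest
same-wave relatives — rather than all thirteen other targets: in arm strata
with ~28 observed rows, fully mutual conditioning saturates the regressions
and degrades the imputations to donor lottery; the restricted sets keep the
models well-determined while preserving within-participant correlation.

Pooling uses Rubin's rules (`pool_rubin()`): pooled estimate = mean of the m
estimates; total variance = within + (1 + 1/m) × between; t-intervals with
Barnard–Rubin degrees of freedom. The fraction of missing information and
the implied loss of efficiency (≈ fmi/m) are reported, with a warning when
the loss exceeds 5% — the working rule under which m = 10 was chosen.

Sensitivity to departures from MAR (delta adjustment, MNAR models) is out of
scope.

## Estimation

Cost and effect differences are estimated jointly by seemingly unrelated
regression (`fit_sur()`): a cost equation (total cost ~ arm + prognostic
covariates) and an effect equation (week-26 endpoint ~ arm + baseline
endpoint + prognostic covariates), estimated by two-step feasible GLS. The
residual 2×2 covariance from per-equation OLS weights the joint system, so
the correlation between cost and effect residuals propagates into the
sampling covariance of (ΔC, ΔE). One FGLS step is used (classical two-step
SUR); inference comes from the bootstrap, so iterating the GLS adds nothing.
When both equations share a regressor set, SUR coincides with
equation-by-equation OLS exactly (the classical identity), which the test
suite verifies to 10⁻⁸.

Prognostic covariates are selected by the 10% change-in-estimate rule
(`select_confounders()`): a candidate (baseline pain, pain duration,
baseline BMI, waiting-list days) is retained when adding it to the arm-only
cost model moves the arm coefficient by more than 10% in relative terms.
Selection runs once, on the first completed dataset, and the selected model
is applied uniformly to all imputations and bootstrap replicates — one fixed
adjusted model, not a per-replicate search. If the base coefficient is
exactly zero the relative criterion is undefined and an absolute floor
(default $1) is used. The effect equation always contains the endpoint's own
baseline, so that variable is never duplicated from the selected set. The
same four prognostic factors adjust every endpoint's equations (uniform
adjustment; the alternative of endpoint-specific subsets is not supported).

## Uncertainty

**Bootstrap.** Within each completed dataset, participants are resampled
with replacement — stratified by arm by default, preserving the observed
group sizes — and the SUR system is refitted; B/m replicates per dataset
(default 5000 total over m = 10) are pooled into one replicate cloud. This
ordering (bootstrap *within* imputations, then pool) preserves
within-imputation correlation and is standard practice in trial-based CEA;
the total-B reading of "5000 replications" is adopted. Degenerate resamples
(single-arm draws under unstratified mode, singular systems) are redrawn and
counted.

**BCa intervals** (`bca_interval()`): bias correction z₀ = Φ⁻¹(fraction of
replicates strictly below the point estimate); acceleration a from the
skewness of leave-one-out jackknife estimates,
a = Σd³ / (6(Σd²)^{3/2}), d the jackknife deviations from their mean; the
interval endpoints are the correspondingly adjusted percentiles, read off by
interpolation of order statistics on the normal-quantile scale. The point
estimate is the Rubin-pooled estimate and the jackknife is computed on the
first completed dataset (the acceleration is a smooth functional and stable
across imputations). With z₀ = a = 0 the interval is the plain percentile
interval; a degenerate replicate cloud collapses to a point; a cloud
entirely on one side of the point estimate makes z₀ infinite and is an
error with a diagnostic rather than a silently extreme interval. The
implementation agrees with the reference implementation in the `boot`
package to 10⁻¹⁰ on mean statistics (tested), but is independent code.

**ICER** = ΔC/ΔE from *unrounded* pooled estimates (rounding before
dividing visibly distorts the ratio when ΔE is small). |ΔE| < 10⁻⁶ endpoint
units is reported as undefined — a value, not an error — and the CEAC is the
preferred summary in that regime.

**CE plane and CEAC.** Replicate pairs are classified into quadrants with
the effect axis oriented toward benefit: QALYs are benefit-positive; pain,
WOMAC, weight and BMI are benefit-negative (a unit gained is a one-unit
reduction), so their ΔE is negated before classification. Exact zeros go to
the cost-increasing / effect-decreasing side (conservative). The CEAC is the
fraction of replicates with strictly positive incremental net monetary
benefit, λ·ΔE_benefit − ΔC > 0; strict inequality makes the λ = 0 value
exactly P(ΔC < 0) and the large-λ limit exactly P(ΔE_benefit > 0), two
identities the tests assert. Default willingness-to-pay grids: 0–100,000
AUD in 1,000-AUD steps for QALYs; 0–5,000 in 50-AUD steps for clinical
endpoints.

**Populations.** Intention-to-treat analyses all randomised participants.
The per-protocol sensitivity analysis keeps intervention participants with
at least six coaching calls and *all* control participants.

## The synthetic-trial generator

`generate_trial()` exists because the underlying participant-level data are
not distributable: it draws trials with the statistical structure the
analysis assumes, with known ground truth, so every pipeline property is
testable. Defaults emulate the published trial's conditions: 119 analysable
participants under 1:1 allocation (the trial randomised 120 and analysed
59 + 60 = 119; the generator defaults to the 119 analysable records and
leaves that one-participant discrepancy to this note), baseline marginals
midway between the published arms (age 61.6 (12.5), pain 6.85 (1.9),
utility 0.65 (0.10), BMI 32.7 (3.3), waiting list lognormal with median 385
days), near-null true effects, and 26-week category cost means of $3,400
(healthcare), $123 (medication) and $250 (absenteeism).

Mechanics worth knowing:

* Utilities at the three timepoints come from a Gaussian copula
  (within-person correlation 0.6), truncated to (0, 1]. The treatment shift
  applies from week 6 onward by default — baseline precedes randomisation —
  so a constant post-baseline shift s implies a true QALY difference of
  23s/52 (the trapezoid of the (0, s, s) profile), which `ground_truth()`
  returns; a `"baseline"` onset (shift at all three points, true difference
  s/2) is available for closed-form checks.
* Costs are built bottom-up as zero-inflated Poisson resource counts valued
  against the unit-cost table, with the intensity scale solved analytically
  so the valued category means equal their targets. Rare hospital
  admissions ($4,422 each) supply the heavy right tail. Healthcare
  intensity is log-linearly tied to baseline pain and to the utility latent
  (mean-one multipliers), so costs are right-skewed and correlated with
  effects; the cost–effect link defaults to 0.2 on the log scale because
  the true correlation is unreported.
* Planted cost effects shift the intervention arm's intensity so the
  expected 26-week category difference equals the requested value exactly;
  the expected wage entering the absenteeism calibration is computed by
  exact integration of the wage bands against the truncated-normal age
  distribution.
* Coaching calls are zero-inflated binomial on {0..10} with moments matched
  to the published mean 4.7 (SD 4.6). Those two moments force
  P(calls ≥ 6) ≈ 0.52, whereas the trial observed 20/59 ≈ 0.34 adherers;
  no distribution on {0..10} satisfies all three figures simultaneously, so
  the moments take precedence and the per-protocol subset is correspondingly
  larger in synthetic data than in the trial.
* `impose_missingness()` deletes follow-up cells and whole inventory blocks
  through logistic models on observed baseline covariates and arm only —
  MAR by construction — with each variable's intercept solved so the
  expected missingness fraction hits its target (defaults: 18–30% on
  effect measures, 52% on 26-week cost inventories, matching the published
  completeness). Within a follow-up wave all deletions share one latent
  uniform per participant, mimicking survey-level nonresponse; this
  reproduces realistic complete-case fractions (~48% complete cost data at
  26 weeks) instead of the vanishing ones independent cell-wise deletion
  would give.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: item-level resource-use frequencies (only category
totals are calibrated), longitudinal dropout processes beyond MAR cell
deletion, MNAR mechanisms, clustering or site effects, digit preferences and
other self-report artefacts, and the exact published point estimates (which
depend on the unavailable individual data).

## Problem sizes and test design

The validation experiments are sized to run on one CPU as part of the
routine test suite: BCa coverage is assessed over 300 simulated trials
(n = 100, normal costs and effects, B = 500), where the 95% interval for ΔC
should cover the truth in 92–98% of runs; parameter recovery over 100
complete-data trials at n = 2000 with a planted ΔC of $500 and ΔE of
0.02 QALYs; and the MAR experiment over 200 replications at trial scale
(n = 119, m = 5) with a strong arm-by-pain missingness interaction, where
multiple imputation must show smaller absolute bias than complete-case
analysis. Under that deliberately harsh MAR mechanism some MI bias remains
(PMM cannot extrapolate beyond the observed donor range in the
heavier-missing arm); the experiment asserts the ordering, not
unbiasedness. End-to-end determinism is checked at full scale
(m = 10, B = 5000): identical seeds yield byte-identical result JSON.

## Known limitations

* The SF-6D tariff is not implemented; utilities must arrive pre-scored.
* Two-step FGLS assumes homoskedastic within-equation errors; gamma/GLM
  cost models and net-benefit regression are deliberately out of scope.
* The BCa acceleration uses the first completed dataset's jackknife rather
  than a jackknife of the full MI pipeline (computationally prohibitive and,
  in the cases tested, immaterial).
* Confounder selection on the first imputation only mirrors the one-fixed-
  model reporting convention but ignores selection uncertainty.
* The generator's per-protocol adherence fraction exceeds the trial's (see
  above); per-protocol synthetic analyses therefore run on a larger active
  arm than the published n = 20.
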