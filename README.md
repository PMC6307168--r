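# trialcea

Trial-based cost-utility and cost-effectiveness analysis for two-arm
randomised trials, built around the economic evaluation of a telephone-based
weight-management service for patients with knee osteoarthritis who are
overweight or obese. The package is aimed at health economists and trial
statisticians who need the full analysis chain — outcome and cost
construction, missing-data handling, joint estimation, and decision-analytic
uncertainty summaries — as reusable, tested code rather than a one-off
analysis script.

## What it computes

For each analysis cell (endpoint × perspective × population) the pipeline
produces the quantities a trial-based economic evaluation reports:

* **QALYs** by area under the piecewise-linear utility curve over 26 weeks:
  utilities measured at weeks 0, 6 and 26 are linearly interpolated and
  integrated (trapezoidal rule), divided by 52 to convert to years.
* **Costs** per participant in AUD-2016, by category: micro-costed
  intervention cost (brief advice + per-coaching-call rate × calls
  received), healthcare services and medications valued against Australian
  unit-cost tariffs, and absenteeism valued by the human capital approach
  (days absent × 7.6 h × age/gender-specific hourly income). Six-week recall
  windows at weeks 6 and 26 are averaged and scaled by 26/6 to the full
  horizon. The societal perspective includes all categories; the healthcare
  perspective excludes absenteeism.
* **Multiple imputation** of missing cost and effect measures by chained
  equations (predictive mean matching, m = 10 completed datasets, stratified
  by arm), with **Rubin's rules** pooling: total variance =
  within + (1 + 1/m) × between.
* **Adjusted differences** Δ*C* and Δ*E* (intervention − control) from
  **seemingly unrelated regression** — a two-equation system estimated by
  feasible GLS so the correlation between cost and effect residuals is
  accounted for — with data-driven confounder selection (10% change-in-
  estimate rule).
* **Uncertainty**: stratified bootstrap of the joint (ΔC, ΔE) distribution
  (5000 replicates pooled across imputations), **BCa** confidence intervals,
  the **ICER** ΔC/ΔE, the cost-effectiveness plane quadrant distribution,
  and **CEACs** — P(λ·ΔE − ΔC > 0) across willingness-to-pay values λ.

Because no participant-level data are distributable, the package includes a
seeded synthetic-trial generator (`generate_trial()`, `impose_missingness()`)
calibrated to the published trial's baseline table and cost scale, with
closed-form ground truth (`ground_truth()`) for validation.

## Worked example

```r
library(trialcea)

params   <- synthetic_params()                      # 119 participants, near-null effects
trial    <- generate_trial(params, seed = 2024)     # complete data + ground truth
observed <- impose_missingness(trial$dataset, params, seed = 2025)

result <- run_analysis(observed, endpoint = "qaly", perspective = "societal",
                       population = "itt", m = 10, B = 5000, seed = 1)
result
#> <cea_result> qaly, societal perspective, itt population (n = 119)
#>   delta_c = 69 AUD (95% BCa CI -2146 to 1728)
#>   delta_e = 0.0024 (95% BCa CI -0.0098 to 0.0143)
#>   ICER = 28,479 AUD/unit
#>   CE plane: NE 38.5%, SE 26.5%, SW 18.2%, NW 16.8%
#>   P(cost-effective) at wtp = 0: 0.45
#>   adjusted for: pain_w0, waitlist_days
```

Reading this: the adjusted societal cost difference is $69 per participant
(intervention minus control) with a wide BCa interval, the QALY difference is
near zero, and the acceptability curve starts at 0.45 — at this seed the
data are compatible with anything from meaningful savings to meaningful extra
cost, exactly the situation the joint (ΔC, ΔE) summaries are designed for.
The generator's true societal cost difference here is $622 (the expected
intervention cost; all other true effects are zero), well inside the
interval. `plot_ce_plane(result)` and `plot_ceac(result)` draw the plane and
the acceptability curve; `write_cea_json(result, path)` serializes the cell
deterministically.

## Package layout

| Area | Functions |
| --- | --- |
| Data model & I/O | `trial_dataset()`, `read_trial_table()`, `write_trial_table()`, `validate_trial()`, `select_population()` |
| Outcomes | `qaly_auc()`, `womac_total()`, `build_effect_table()` |
| Costing | `default_unit_costs()`, `assemble_costs()`, `intervention_cost()`, `value_healthcare()`, `value_medications()`, `absenteeism_cost()`, `interpolate_period_cost()`, `cpi_adjust()` |
| Imputation | `mice_impute()`, `pool_rubin()` |
| Estimation | `fit_sur()`, `select_confounders()`, `unadjusted_differences()` |
| CEA | `run_analysis()`, `bootstrap_ce()`, `bca_interval()`, `icer()`, `quadrant_distribution()`, `ceac()`, `plot_ce_plane()`, `plot_ceac()` |
| Synthetic trials | `synthetic_params()`, `generate_trial()`, `impose_missingness()`, `ground_truth()` |

The methods vignette (`vignettes/trial-cea-methods.Rmd`) documents the
statistical model, every tunable parameter and numerical convention, and the
design decisions behind them.
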