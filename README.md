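# boxcua

Trial-based cost-utility analysis of an eHealth remote-monitoring
programme ("The Box") versus regular outpatient follow-up after acute
myocardial infarction (AMI), from a department-of-cardiology perspective
over one year, in 2020 euros.

## Who this is for

Health-economics analysts and methodologists who want a reproducible,
tested implementation of the standard trial-based cost-utility toolchain
— patient-level micro-costing, QALY estimation from patient-reported
utilities with multiple imputation, and probabilistic cost-effectiveness
analysis — together with a synthetic trial generator calibrated to the
published arm-level summaries of the Box trial, so that every stage can
be exercised end to end without access to the (undeposited) patient-level
data.

## The analysis in brief

For each patient *i* with per-item resource counts and costs, the
department-perspective total is the sum of the priced items (device,
visits, Holter/echo procedures, admissions, revascularisations, allocated
technical support). Utilities *u*(1), *u*(6), *u*(12) measured at months
1, 6 and 12 (SF-36 derived; on the 0–1 dead/perfect-health scale) give a
one-year QALY by the trapezoidal area under the piecewise-linear utility
curve, carrying the 1-month value back to baseline:

    QALY = [ u(1)·1 + (u(1)+u(6))/2 · 5 + (u(6)+u(12))/2 · 6 ] / 12

Missing utilities are multiply imputed (m = 20) by Bayesian
normal-regression draws chained over timepoints, with the randomisation
arm, age, sex, index event and log peak troponin as predictors, and
pooled by Rubin's rules. Uncertainty in the incremental cost ΔC and
incremental effect ΔE (intervention − control) comes from a
nonparametric bootstrap (B = 1000) stratified by arm, cycling over the
imputed datasets. The cost-effectiveness acceptability curve reports, for
each willingness-to-pay λ, the fraction of bootstrap pairs with positive
incremental net monetary benefit λ·ΔE − ΔC (ties count as not
cost-effective); the Dutch threshold range is €20,000–€80,000 per QALY.
A sensitivity analysis adds patient-related costs: a 7 km round trip at
€0.19/km plus €3.20 parking plus 4.5 h of lost time per in-office visit,
0.5 h per e-visit, both valued at a 70/30 blend of €37.05 and €13.33
hourly wages, and 10 min/week of home measurements at the non-productive
wage.

## Worked example

```r
library(boxcua)
res <- run_base_case(seed = 4, currency = "both")   # simulates, costs, imputes, bootstraps
print(res)
```

```
Cost-utility analysis (department perspective, 88 intervention / 92 control patients)
  mean total cost: €2,249 (US $2,473) ± €1,799 (US $1,977) intervention vs €2,812 (US $3,091) ± €2,642 (US $2,905) control
  cost difference (control - intervention): €562 (US $618) [95% CI €-105 (US $-116) to €1,230 (US $1,352)], p = 0.10
  QALYs: 0.74 intervention vs 0.71 control (difference 0.032, p = 0.162)
  ICER: dominant 
  CEAC: minimum probability cost-effective 0.945 over 201 WTP values
```

One simulated trial of 100 + 100 enrolled patients (12/8 early dropouts
excluded by the modified intention-to-treat filter) yields arm mean
costs, the incremental cost with its pooled-variance t interval, pooled
QALYs, the ICER quadrant (here: the intervention is *dominant* — cheaper
and more effective), and the minimum CEAC probability over the
€0–100,000/QALY grid. The sensitivity run adds the patient-related row:

```r
sens <- run_sensitivity(seed = 4)
sens$cost_table[sens$cost_table$item_id %in% c("patient_related", "total"),
                c("int_mean", "ctl_mean", "difference", "p_value")]
#>    int_mean ctl_mean difference p_value
#> 14   416.42   579.06     162.64    0.00
#> 15  2665.83  3390.81     724.98    0.03

extrapolate_national(-562)$savings_eur   # ~19.1 million EUR/year at 34,000 AMI patients
```

`run_base_case(..., out_dir = "out")` writes the cost table, QALY
summary, CE-plane draws (`delta_cost,delta_qaly`) and CEAC
(`wtp,probability`) as CSV plus a JSON manifest with the seed and file
hashes; identical configuration and seed give byte-identical files.
`inst/scripts/run_cua.R` wraps the same calls for shell use.

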