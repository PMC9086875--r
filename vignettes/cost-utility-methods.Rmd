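---
title: "Methods: trial-based cost-utility analysis of remote monitoring after AMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis of remote monitoring after AMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxcua)
```

## The problem

After an acute myocardial infarction (AMI), patients are conventionally
followed for a year with four in-office outpatient visits, serial ECGs,
Holter monitoring and echocardiography. A remote-monitoring programme
("The Box": home blood-pressure monitor, weight scale, single-lead ECG
device and step counter, with two of the four visits replaced by video
e-visits) changes both what the follow-up costs a cardiology department
and, potentially, patients' quality of life. This package implements the
economic comparison of the two strategies as a trial-based cost-utility
analysis: a one-year horizon, a department-of-cardiology perspective in
the base case, costs in 2020 euros, and quality-adjusted life years
(QALYs) as the effect measure, with a patient-perspective extension as a
sensitivity analysis.

Because the underlying trial's patient-level records are not publicly
deposited, the package pairs the analysis pipeline with a synthetic
trial generator calibrated to the trial's published arm-level summaries.
Everything downstream of the generator is the ordinary pipeline a real
dataset would flow through; `run_base_case(records = your_data)` accepts
external patient-level CSV data with the same columns.

## Costing model

Each resource item has a unit cost in the price table
(`default_price_table()`): the device from bills, procedures at hospital
list prices, revascularisations from the Dutch Healthcare Authority
lists, admissions (per night) and nurse-practitioner contacts from the
Dutch costing manual. Two unit costs are micro-costed rather than
tariffed, because no reference price exists for an e-visit:

* `unit_cost_in_office()`: direct components times a 44% overhead
  multiplier (the standard Dutch hospital overhead);
* `unit_cost_evisit()`: yearly video-system subscription divided by full
  capacity (5500 e-visits/year) times a reduced 22% overhead — an
  e-visit consumes no cleaning and less housing.

Shared support (a 0.5-FTE technician plus billed technical support) is
allocated equally over the intervention patients
(`allocate_shared_cost()`). All prices carry a calendar year and pass
through a consumer-price-index conversion to 2020 euros
(`inflate_to_2020()`); entries already in 2020 euros use index ratio 1,
keeping one code path. Dollar figures use the fixed rate €1 = US $1.0994.
Amounts are kept at full precision internally; rounding is a
presentation concern.

The sensitivity analysis adds patient-related costs
(`patient_cost_params()`), with defaults and units:

| parameter | default | unit | rationale |
|---|---|---|---|
| travel distance | 7 | km one-way | average home–hospital distance; costed round-trip |
| km rate | 0.19 | EUR/km | Dutch costing manual |
| parking | 3.20 | EUR/visit | Dutch costing manual |
| time, in-office visit | 4.5 | h | includes travel and waiting |
| time, e-visit | 0.5 | h | call duration only |
| productive fraction | 0.70 | — | median age 59: ~30% retired |
| hourly wage, productive | 37.05 | EUR/h | productivity-cost tariff |
| hourly wage, non-productive | 13.33 | EUR/h | leisure-time tariff |
| device use | 10 | min/week | valued at the non-productive wage (off-hours) |

Travel is costed round-trip; a one-way reading of the 7 km distance
cannot reproduce the published control-arm patient-cost mean (€570),
while the round trip lands within 0.1%. The 70% productive share is
applied as an expected blended wage per hour rather than by sampling
worker status per patient — the two are equivalent in expectation and
the blended form keeps the deterministic cost model deterministic.

## QALYs, missingness and multiple imputation

Utilities are measured at months 1, 6 and 12 on the 0–1 scale (1 =
perfect health, 0 = as bad as dead). `qaly_auc()` integrates the
piecewise-linear utility curve over months 0–12 and divides by 12.
The measurement schedule leaves month 0–1 undefined; the package carries
the 1-month utility back to baseline (a rectangle of width 1 month),
the simplest convention consistent with the published arm QALY
magnitudes. Deaths during follow-up are retained by the
modified-ITT filter; representing a death as zero utility from the month
of death onward is done by recording observed zeros in the utility
columns before imputation — the generator itself does not simulate
deaths.

Missing utilities are handled by multiple imputation
(`impute_utilities()`): for each of m = 20 copies, each timepoint is
imputed in temporal order by a Bayesian linear regression draw (residual
variance from the scaled inverse-χ², coefficients from their normal
posterior, then a predictive draw per missing cell, clipped to [0, 1]).
Predictors are the randomisation arm, age, sex, index event (STEMI vs
NSTEMI), log peak troponin, and all earlier utilities. Two choices
matter:

* **The arm is always in the imputation model.** Omitting the analysis
  grouping shrinks imputed values toward the pooled mean and attenuates
  the between-arm QALY difference (in calibration runs, by roughly
  0.007 of the 0.049 difference) — the standard congeniality requirement
  for MI.
* **Draws are stochastic, not deterministic fits**, so between-imputation
  variance is non-zero and Rubin's rules (`pool_rubin()`) yield honest
  total variances: total = within + (1 + 1/m) · between, with the classic
  large-sample degrees of freedom.

Arm means and the arm difference are pooled over imputations
(`trial_qaly()`). The SF-36-to-utility scoring algorithm (SF-6D) is
licensed and not shipped; `sf6d_scorer()` is a hook that refuses with a
notice, and `toy_linear_scorer()` exists only so the wiring is testable.

## Bootstrap, CE plane and CEAC

`bootstrap_ce()` resamples patients with replacement *within each arm at
the original arm sizes*. The stratification preserves the randomisation
structure; an unstratified resample would mix arm-size variation into
the uncertainty. Each replicate uses one completed dataset, cycling over
the m imputations, so imputation uncertainty propagates into the draws
without the cost of a nested MI-within-bootstrap scheme (a documented
approximation: the between-imputation component enters through cycling
rather than through re-imputation of each resample).

The CEAC (`ceac()`) is the fraction of bootstrap (ΔC, ΔE) pairs with
strictly positive net monetary benefit λ·ΔE − ΔC; ties count as not
cost-effective (conservative). Two invariants pin the implementation
down: the curve equals the `nmb() > 0` path exactly at every λ, and its
endpoints are the dominance fractions P(ΔC < 0) at λ = 0 and P(ΔE > 0)
as λ → ∞. The default grid, €0–100,000 in €500 steps, covers the Dutch
willingness-to-pay range (€20,000–€80,000/QALY) with margin. The sign
convention is intervention − control everywhere; a published "cost
reduction of €471" appears here as ΔC = −471.

## What the synthetic generator emulates — and what it does not

`default_config()` encodes the study conditions: 100 patients enrolled
per arm; 12/8 early dropouts removed by `apply_mitt_filter()` (leaving
88/92); twelve resource items whose expected per-patient costs reproduce
the published pooled cost table; and utility trajectories with arm means
(0.745, 0.740, 0.735) and (0.710, 0.685, 0.680), which the trapezoid
maps to one-year QALYs of 0.740 and 0.691.

Per item, costs follow a two-part model: a count distribution times a
cost-per-event severity. Scheduled visit items use a low-dispersion
count (floor plus Bernoulli fraction plus a mean-preserving ±1 jitter
with probability 0.15, chosen to approximate the published visit-item
cost SDs); rare inpatient items use Poisson or Bernoulli counts with
right-skewed gamma severities (hospitalization cv 0.5 at ~€684/night and
admission probability 0.04; catheterization and PCI cv 0.3 at list
prices). Where the published counts-times-price products contradict the
published per-patient mean costs (the visit rows, catheterization), the
mean-cost column is taken as authoritative, since arm totals sum over
it; single-vessel PCI counts are used as 4 intervention / 10 control,
the only assignment consistent with the published arm means. The
resulting expected totals are €2412 (intervention) and €2887 (control)
against published totals of €2417/€2888 — the residual is the published
table's own internal rounding.

Utilities are drawn from an exchangeable trivariate normal (correlation
0.6, SD 0.18) and clipped to [0, 1]. Naive clipping would pull the arm
means down by up to 0.02 at these parameters, so the latent means are
calibrated by inverting the closed-form clipped-normal mean
(`uniroot` at configuration time); post-clip marginal means then equal
the configured targets exactly. Missingness is missing-at-random with a
marginal rate of 0.2 per timepoint and a logistic dependence on age and
the most recent *observed* utility — strong enough that complete-case
analysis is visibly biased and the imputation stage is genuinely
exercised.

Covariates not published beyond summary level are filled in with
plausible AMI-trial values: age ~ N(59.5, 9.5²) (published median 59,
IQR 53–66), 78% male (published), 55% STEMI and log-normal peak troponin
(invented plumbing; they drive only the MAR mechanism and the imputation
design matrix).

The generator deliberately does **not** emulate: correlation between
cost and utility within patient (the two are independent given the arm),
clinical-event survival processes or deaths, telemetry data streams,
between-item cost correlation, or non-normal utility shapes beyond
clipping. Passing calibration tests therefore shows that the pipeline
recovers the moments the generator encodes — not that it would recover
every feature of the real trial's joint distribution.

## Numerical and degenerate-case choices

* QALY formula reduces to (3.5·u1 + 5.5·u6 + 3·u12)/12; it agrees with
  fine-grid numerical integration to 1e-12 and is exact, not quadrature.
* Zero-variance groups (e.g. a deterministic device cost in both
  patients compared) short-circuit the t test: difference 0 gives p = 1,
  a non-zero difference between constant groups gives a degenerate
  interval at the point estimate.
* An all-dropout dataset filters to an empty analysis set with a warning
  at the filter and an error at the pipeline.
* A timepoint entirely missing within an arm stops imputation with a
  diagnostic naming the timepoint and arm, rather than extrapolating.
* Bootstrap, imputation and generation consume seeds independently
  (the pipeline derives fixed offsets from the run seed), so
  `(config, seed)` determines every output file byte-for-byte.

## Replication sizes

The shipped checks simulate trials of 200 enrolled patients and average
headline quantities over 20 seed-replications (the acceptance script
uses 250 for the cost and QALY means, a 10-trial median for the CEAC
minimum, and 20 full sensitivity runs); a single end-to-end run with
B = 1000 bootstrap replicates and m = 20 imputations takes well under a
second, so all sizes are set by Monte-Carlo precision, not cost.

## Known limitations

* The published patient-related cost figures are not mutually consistent
  at full precision: the deterministic model reproduces the control mean
  (€570) to 0.1% and the intervention mean (€426) to 0.9%, but their
  difference (published as €144) computes to €140 from the published
  visit frequencies — no parameterisation consistent with the stated
  0.5 h e-visit time can match all three at once.
* At the λ = 0 end of the CEAC grid the curve equals P(ΔC < 0), which
  under the published cost dispersion (SE of the difference ≈ €380) is
  ~0.89 even at the published point estimate; re-simulated trials spread
  around that, so the "probability above 0.9 over the whole grid"
  headline holds robustly only from the Dutch threshold range upward
  (every simulated trial exceeds 0.95 there).
* Department-perspective costing ignores care outside cardiology by
  design; the combined perspective adds patient-related costs but not
  productivity losses beyond visit and device time.
* The imputation model is linear-normal on a clipped outcome; with 20%
  missingness the residual bias is well inside Monte-Carlo noise, but
  heavier missingness or floor/ceiling-concentrated utilities would call
  for a latent-truncation or PMM imputer.
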