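---
title: "Methods: the ICD cost-utility cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ICD cost-utility cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdcea)
```

## The decision problem

Patients with NYHA class II–III heart failure, left-ventricular systolic
dysfunction and an ejection fraction below 35% are at elevated risk of sudden
cardiac death (SCD). An implantable cardioverter-defibrillator (ICD) on top
of optimal pharmacological therapy (OPT) reduces both all-cause and sudden
cardiac mortality, at a substantial up-front device and implantation cost and
with recurring complication and replacement costs. The package quantifies the
trade-off for a cohort entering at age 60, from a health-system perspective,
as an incremental cost-effectiveness ratio (ICER, USD per quality-adjusted
life year), compared against willingness-to-pay (WTP) thresholds of 1x and 3x
GDP per capita (USD 6,308 and 19,139 for Colombia in 2017).

## Model structure

The model is a decision tree feeding an annual-cycle Markov cohort model.

**Entry (decision tree).** OPT patients enter the `well` state. ICD patients
either die post-operatively (a degenerate probability of 0 in the base case:
the pooled trial evidence records 0 events in 2,774 implantations) or enter
`well`; the ICD arm is charged the device price plus implantation procedure
plus post-implant hospitalization at cycle 0.

**States.** One well state; three transient complication states (device
movement, severe infection, lead fracture/displacement); five absorbing dead
states split by cause (sudden cardiac, non-sudden cardiac, non-cardiac,
operative, infection). Transient complication states carry one cycle of
decremented utility and added cost and then rejoin the well pathway; the
complication hazard recurs every cycle in the ICD arm.

**Transitions.** Each cycle, every living patient faces the cause-specific
death probabilities; ICD-arm survivors then draw a complication with
probability 0.062, split 0.5 / 0.2 / 0.3 between movement, infection and
fracture (the fracture share is the residual of the two published conditional
shares). Patients entering the infection state die of it within the same
cycle with probability 0.21.

**Mortality decomposition.** The trial evidence supplies annual all-cause
and sudden-cardiac mortality per arm; the background schedule supplies the
age-specific non-cardiac probability q(age). Non-sudden cardiac death is the
residual

> p_nonsudden(age) = max(0, p_all_cause − p_scd − q(age)),

floored at zero with a warning. A consequence worth knowing: as long as
q(age) stays below p_all_cause − p_scd (true for several decades under the
default schedule), total mortality each cycle equals the trial all-cause
value, so the deterministic results are insensitive to the background table.
A second consequence: sweeping or sampling the SCD probability re-attributes
deaths between causes without changing totals, so it has exactly zero effect
on costs, QALYs and the ICER — visible as zero-span rows in the tornado
table.

**Accrual and discounting.** Living patients accrue the annual OPT
management cost; infection occupants add infection management plus a new
device with implantation and hospitalization; movement/fracture occupants add
the fracture/displacement cost; the well state accrues utility 0.845 and
complication states 0.75. All living ICD patients are charged a device
replacement at cycles that are whole multiples of the replacement interval
(default 5 years) strictly inside the horizon — for a 10-year run, cycle 5
only. Cycle *t* values are divided by (1+r)^t with cycle 0 undiscounted, at
3% for costs and 3.5% for QALYs. No half-cycle correction is applied; with
annual cycles and these mortality levels the correction would shift both arms
by similar amounts and is omitted for transparency.

## Parameters

All parameters live in a single `study_config` object
(`fixture_config("base_case")`, or the identical packaged YAML at
`base_case_config_path()`). Probabilities and the well utility carry beta
pseudo-count distributions (alpha = events, beta = non-events); costs carry
uniform min–max ranges in 2017 USD; the death-from-infection beta
(alpha 1.93, beta 7.27) is recovered from a mean of 0.2098 and SD of 0.1275
by method of moments (`beta_from_moments()`).

| parameter | base | source distribution |
|---|---|---|
| OPT all-cause mortality (annual) | 0.284 | Beta(604, 1522) |
| OPT sudden cardiac death | 0.108 | Beta(317, 2605) |
| ICD all-cause mortality | 0.178 | Beta(385, 1790) |
| ICD sudden cardiac death | 0.037 | Beta(110, 2825) |
| ICD operative death | 0 | Beta(0, 2774), point mass at 0 |
| ICD complication (annual) | 0.062 | Beta(169, 2554) |
| movement / infection share | 0.5 / 0.2 | Beta(16, 16) / Beta(10, 40) |
| death from infection | 0.21 | Beta(1.93, 7.27) |
| utility well / complication | 0.845 / 0.75 | Beta(6.164, 1.131) / fixed |
| OPT annual management | 313.04 | U(282.08, 343.95) |
| device price | 7,259.46 | U(6,539.44, 7,793.12) |
| implant procedure | 300.28 | U(289.80, 337.59) |
| post-implant hospitalization | 73.39 | U(70.11, 84.01) |
| major infection | 194.17 | U(184.57, 223.73) |
| fracture/displacement | 187.83 | U(180.60, 213.83) |

The base-case ICD all-cause probability 0.178 differs from its count mean
385/2175 = 0.17701 in the third decimal; validation flags (but accepts)
base-vs-mean gaps up to 0.002.

**Replacement cost policy.** The original costing states that replacement
covers the generator battery only, excluding electrodes and wires, but prints
no battery-only price. The package therefore defaults to charging the full
device price at replacement (`replacement_cost_policy = "full_device"`, the
only published quantity), with `"device_plus_procedure"` and custom-USD
policies available. This choice biases the ICD-arm cost upward; see
*Known limitations*.

## The synthetic background life table

The original evaluation adjusted non-cardiac mortality with national
age-specific life tables that were never published. The package emulates them
with a two-parameter Gompertz schedule,

> q(age) = 1 − exp(−a · exp(b · (age − 60))),

calibrated by `calibrate_life_table(q_start, doubling_time, ...)`: the
default fixes q(60) = 0.012 (a 60-year-old's typical annual background risk)
and a hazard doubling time of 8 years (the classic adult mortality gradient).
These two values were chosen once, on demographic grounds, and are not tuned.
What the generator reproduces: smooth, monotone, exponentially rising
background risk. What it cannot reproduce: the exact level and shape of the
original national table, cause-of-death coding, or cohort effects —
so tests passing under this schedule validate the mechanics, not the original
table. Under the decomposition above, the deterministic base case is in any
case insensitive to the schedule over a 10-year horizon.

## Sensitivity analyses

**One-way / tornado.** `one_way()` re-runs both arms with one parameter at
each end of its range; `tornado()` sorts the induced ICER spans. Default
ranges: published min–max for costs, central 95% beta intervals for
probabilities and the well utility (a documented convention — the original
publishes explicit ranges only for costs). Under these defaults the two
all-cause mortality parameters dominate every cost; only the well utility,
whose published Beta(6.164, 1.131) is very diffuse (95% interval roughly
0.53–0.99), spans wider. When the well utility is swept below the
complication utility, the latter is dragged down with it so the preference
ordering of states is preserved.

**Scenarios.** `scenario()` applies dotted-path overrides
(e.g. `list("econ.horizon_years" = 20)`); `fixture_config()` packages the
named horizon-5/20 and 7-year-replacement variants. The subgroup
(ischemic/non-ischemic) configurations ship as stubs with `NA` mortality
probabilities that refuse to run until the user substitutes values, because
the subgroup inputs were never published.

**Break-even price.** `threshold_device_price()` finds the device price at
which the ICER equals a WTP threshold. The ICER is monotone increasing in
the price (charged at entry, in infection management and at replacements), so
the root is unique; it is bracketed on [0, 5x base price] and solved with
Brent's method (`stats::uniroot`) to 1 USD.

**Probabilistic sensitivity analysis.** `run_psa()` draws every probability
and the well utility from its beta, every cost from its uniform,
independently across parameters and arms (the published parameterization is
by independent per-arm counts; this ignores the trial-level correlation
between arms and between all-cause and sudden-cardiac mortality — a
documented caveat that widens the incremental-QALY distribution). Structural
guards: SCD is capped at all-cause mortality; movement/infection shares are
rescaled proportionally in the rare draws summing above 1; the sampled
complication utility is capped at the sampled well utility; operative death
stays at its point mass 0. `ceac()` reports, per WTP value, the fraction of
draws with positive incremental net monetary benefit, with its binomial
Monte Carlo standard error (≤ 0.005 at n = 10,000 near p = 0.95). The seed
is a required, logged input (default 20170101). `collapse_to_means()`
replaces every distribution by its mean; a collapsed PSA reproduces the
deterministic run of the collapsed configuration exactly, which is tested to
1e-9.

## Numerical choices

- Cohort mass is asserted to sum to 1 within 1e-12 after every transition.
- For horizons up to 3 cycles the engine is verified to 1e-10 against an
  independent brute-force enumeration of all state paths.
- Degenerate inputs: alpha = 0 betas are point masses; zero-width cost
  ranges are allowed; zero discount rates reproduce undiscounted sums
  exactly; a replacement interval longer than the horizon simply never
  triggers.
- Problem sizes: deterministic runs are 5–20 annual cycles and complete in
  milliseconds; the shipped analyses use the study-standard 10,000 PSA draws
  (about 20 s), and test-suite property grids use hundreds of draws where
  distributional shape is not at issue.

## Reproduction of the original results, and known limitations

The package reproduces the original per-arm totals closely (costs and QALYs
within about 3–6% in the base case, as the acceptance checks compute), but
the original *incremental* results are not reproducible within the package's
own 10% checks, and the corresponding acceptance tests are deliberately left
failing rather than loosened. The analysis of why:

1. **Two inconsistent sources for the ICD-arm mortality.** The original
   methods state that ICD probabilities were obtained by multiplying the OPT
   baseline by relative risks 0.73 (all-cause) and 0.40 (SCD), which gives
   0.2073 and 0.0432; the parameter table instead prints the pooled count
   rates 0.178 and 0.037. The two readings bracket the published incremental
   QALY (0.76): the printed counts give about 0.98, the RR derivation about
   0.65. The package's base case follows the printed table (and samples the
   printed counts in the PSA, keeping the deterministic and probabilistic
   analyses consistent); `apply_relative_risks()` provides the other reading.
   Under the printed values the published per-arm QALY total for the ICD arm
   (3.3653) is not attainable by any constant or monotonically rising annual
   mortality schedule that also matches the OPT arm, which is why the gap
   cannot be closed by the background life table.
2. **Unpublished replacement (battery-only) cost**, handled as described
   above; charging the full device price raises the incremental cost by
   roughly 5%.
3. **Unpublished life table and cycle conventions** (half-cycle handling,
   end-of-horizon replacement) of the original implementation.

Because the ICER divides one small difference by another, per-arm errors of a
few percent amplify several-fold in the incremental quantities: the base-case
ICER computed here is about 17% below the original figure, scenario ICERs are
15–20% below, the break-even price about 24% above, and the PSA acceptability
at 3x GDP about 3 points above. The qualitative conclusions all agree: the
ICD strategy is cost-effective at 3x but not 1x GDP per capita over 10 years;
shortening the horizon to 5 years overturns the decision; longer horizons
and longer replacement intervals strengthen it; the mortality probabilities
are the most influential parameters.
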