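# icdcea

Cost-utility analysis of an implantable cardioverter-defibrillator (ICD)
added to optimal pharmacological therapy (OPT), versus OPT alone, for
patients with NYHA class II–III heart failure, left-ventricular systolic
dysfunction and ejection fraction < 35%, from a health-system perspective.
The package is aimed at health economists and HTA analysts who want the full
model — parameters, engine, sensitivity analyses — as tested, scriptable
code rather than a point-and-click decision-tree file.

## The model

A decision tree for the implantation phase (operative death vs. survival,
plus the up-front device, procedure and hospitalization costs) feeds an
annual-cycle Markov cohort model with states

> well, three transient ICD complications (device movement, severe
> infection, lead fracture/displacement), and five absorbing dead states
> (sudden cardiac, non-sudden cardiac, non-cardiac, operative, infection).

Per cycle, non-sudden cardiac mortality is the residual
`max(0, p_all_cause − p_scd − q(age))`, where `q(age)` is a synthetic
Gompertz background life table calibrated to q(60) = 0.012 with an 8-year
hazard doubling time. Costs discount at 3% per year and QALYs at 3.5%
(cycle 0 undiscounted); the device is replaced every 5 years. Decision
statistics:

- ICER = ΔCost / ΔQALY (USD per QALY), compared with willingness-to-pay
  thresholds of 1x and 3x GDP per capita (USD 6,308 / 19,139, 2017);
- net monetary benefit NMB(λ) = λ·QALY − Cost;
- CEAC(λ) = P(ΔNMB > 0) over 10,000 Monte Carlo draws — beta distributions
  for probabilities and the well utility, uniform for costs;
- break-even device price: the price at which ICER(price) = λ, solved by
  root bracketing to 1 USD.

All base-case inputs ship in the package (`fixture_config("base_case")`,
identical to `inst/extdata/table1_base_case.yaml`).

## Worked example

```r
library(icdcea)
cfg <- load_config(base_case_config_path())
run <- run_comparison(cfg)
export_ce_table(run, "ce_table.csv")
```

which prints (via `analysis/01_base_case.R`):

```
Base case (10-year horizon, 3%/3.5% discounting, 5-year replacement)
  strategy     cost incremental_cost   qaly incremental_qaly  icer
       OPT   999.79               NA 2.6728               NA    NA
 OPT + ICD 11623.67         10623.88 3.6508            0.978 10863

The ICD strategy costs USD 10624 more and yields 0.9780 more QALYs,
an ICER of USD 10863 per QALY gained — below the 3x-GDP threshold of USD 19139,
but above the 1x-GDP threshold of USD 6308.
```

Read: over 10 years, a cohort member on OPT alone accrues ~1,000 USD of
discounted costs and 2.67 discounted QALYs; adding the ICD costs ~10,600 USD
more (device, implantation, one replacement, complications) and yields ~0.98
extra QALYs, i.e. ~10,900 USD per QALY gained — cost-effective at the 3x-GDP
threshold, not at 1x.

The numbered scripts under `analysis/` run the full study: base case and
traces (`01`), horizon and replacement scenarios (`02`), tornado (`03`),
break-even device price (`04`), and the PSA with its acceptability curve
(`05`). Each writes CSV tables and a JSON manifest under `results/`.

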