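schema: icdcea-config-1
economics:
  horizon_years: 10
  discount_rate_costs: 0.03
  discount_rate_qalys: 0.035
  start_age: 60
  replacement_interval_years: 5
  wtp_low: 6308.0
  wtp_high: 19139.0
  exchange_rate_cop_per_usd: 2951.320000000000164
probabilities:
  OPT:
    operative_death:
      base: 0.0
    all_cause:
      base: 0.284
      alpha: 604.0
      beta: 1522.0
    sudden_cardiac:
      base: 0.108
      alpha: 317.0
      beta: 2605.0
  ICD:
    operative_death:
      base: 0.0
      alpha: 0.0
      beta: 2774.0
    all_cause:
      base: 0.178
      alpha: 385.0
      beta: 1790.0
    sudden_cardiac:
      base: 0.037
      alpha: 110.0
      beta: 2825.0
    complication:
      base: 0.062
      alpha: 169.0
      beta: 2554.0
    movement_given_complication:
      base: 0.5
      alpha: 16.0
      beta: 16.0
    infection_given_complication:
      base: 0.2
      alpha: 10.0
      beta: 40.0
    death_given_infection:
      base: 0.21
      alpha: 1.929775536055363
      beta: 7.268391937993078
utilities:
  well:
    base: 0.845
    alpha: 6.164
    beta: 1.131
  complication:
    base: 0.75
costs:
  opt_annual:
    base: 313.04000000000002
    min: 282.079999999999984
    max: 343.949999999999989
  device_price:
    base: 7259.460000000000036
    min: 6539.4399999999996
    max: 7793.119999999999891
  implant_procedure:
    base: 300.279999999999973
    min: 289.800000000000011
    max: 337.589999999999975
  post_implant_hospitalization:
    base: 73.390000000000001
    min: 70.109999999999999
    max: 84.010000000000005
  major_infection:
    base: 194.169999999999987
    min: 184.569999999999993
    max: 223.72999999999999
  fracture_displacement:
    base: 187.830000000000013
    min: 180.599999999999994
    max: 213.830000000000013
replacement_cost_policy: full_device
life_table:
  q_start: 0.012
  doubling_time_years: 8.0
meta:
  scenario: base_case

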