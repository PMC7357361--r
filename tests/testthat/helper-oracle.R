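# Independent brute-force oracle: enumerate every state path of the cohort
# model with multiplied branch probabilities and sum per-cycle accruals.
# Written as an explicit event tree, deliberately separate from the engine's
# vectorised bookkeeping, for horizons small enough to enumerate (<= 3-4).

oracle_branches <- function(state, arm, cfg, age) {
  sn <- state
  if (startsWith(sn, "dead")) return(stats::setNames(1, sn))
  p <- cfg$probabilities[[arm]]
  q <- cfg$life_table$q[match(age, cfg$life_table$age)]
  scd <- p$sudden_cardiac$base
  ns <- max(0, p$all_cause$base - scd - q)
  surv <- 1 - scd - ns - q
  br <- c(dead_sudden_cardiac = scd, dead_nonsudden_cardiac = ns,
          dead_noncardiac = q)
  if (arm == "OPT") {
    br <- c(br, well = surv)
  } else {
    pc <- p$complication$base
    pm <- p$movement_given_complication$base
    pi_ <- p$infection_given_complication$base
    pdi <- p$death_given_infection$base
    br <- c(br,
            well = surv * (1 - pc),
            comp_movement = surv * pc * pm,
            comp_fracture = surv * pc * (1 - pm - pi_),
            comp_infection = surv * pc * pi_ * (1 - pdi),
            dead_infection = surv * pc * pi_ * pdi)
  }
  br[br > 0]
}

oracle_accrual <- function(state, arm, cfg, cycle) {
  cs <- cfg$costs
  cost <- 0; qaly <- 0
  if (!startsWith(state, "dead")) {
    cost <- cs$opt_annual$base
    if (state == "comp_infection")
      cost <- cost + cs$major_infection$base + cs$device_price$base +
        cs$implant_procedure$base + cs$post_implant_hospitalization$base
    if (state %in% c("comp_movement", "comp_fracture"))
      cost <- cost + cs$fracture_displacement$base
    if (arm == "ICD" && cycle >= 1 &&
        cycle %% cfg$econ$replacement_interval_years == 0) {
      pol <- cfg$replacement_cost_policy
      cost <- cost + if (is.numeric(pol)) pol else switch(pol,
        full_device = cs$device_price$base,
        device_plus_procedure = cs$device_price$base + cs$implant_procedure$base)
    }
    qaly <- if (state == "well") cfg$utilities$well$base else
      cfg$utilities$complication$base
  }
  c(cost = cost, qaly = qaly)
}

# Expected discounted (cost, qaly) totals by exhaustive path enumeration.
oracle_run_arm <- function(arm, cfg) {
  horizon <- cfg$econ$horizon_years
  rc <- cfg$econ$discount_rate_costs
  rq <- cfg$econ$discount_rate_qalys
  entry_cost <- if (arm == "ICD")
    cfg$costs$device_price$base + cfg$costs$implant_procedure$base +
      cfg$costs$post_implant_hospitalization$base else 0
  p_op <- if (arm == "ICD") cfg$probabilities$ICD$operative_death$base else 0
  start <- c(well = 1 - p_op)
  if (p_op > 0) start <- c(start, dead_operative = p_op)

  total <- c(cost = entry_cost, qaly = 0)
  recurse <- function(state, cycle, prob) {
    acc <- oracle_accrual(state, arm, cfg, cycle)
    total["cost"] <<- total["cost"] + prob * acc["cost"] / (1 + rc)^cycle
    total["qaly"] <<- total["qaly"] + prob * acc["qaly"] / (1 + rq)^cycle
    if (cycle == horizon - 1) return(invisible())
    br <- oracle_branches(state, arm, cfg, cfg$econ$start_age + cycle)
    for (nm in names(br)) recurse(nm, cycle + 1, prob * br[[nm]])
  }
  for (nm in names(start)) recurse(nm, 0, start[[nm]])
  total
}
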