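# The cohort engine: a decision tree for the implantation phase feeding an
# annual-cycle Markov model. The cohort is tracked as state-occupancy
# fractions; costs and QALYs accrue per cycle at the state occupied at the
# start of the cycle and are discounted by 1/(1+r)^cycle with cycle 0
# undiscounted (no half-cycle correction).

#' Markov state names
#'
#' Living states: `well` and the three transient complication states
#' (device movement, severe infection, lead fracture/displacement), which
#' carry one cycle of decremented utility and added cost and then return to
#' `well`. Dead states are absorbing and split by cause so the mortality
#' decomposition is auditable in traces.
#' @return Character vector of the nine state names, in trace column order.
#' @export
state_names <- function() {
  c("well", "comp_movement", "comp_infection", "comp_fracture",
    "dead_sudden_cardiac", "dead_nonsudden_cardiac", "dead_noncardiac",
    "dead_operative", "dead_infection")
}

new_state <- function() {
  stats::setNames(numeric(9L), state_names())
}

check_state <- function(state) {
  if (any(state < -1e-12) || any(state > 1 + 1e-12))
    stop("state fractions outside [0, 1]")
  if (abs(sum(state) - 1) > 1e-12)
    stop("state fractions do not sum to 1 (off by ", sum(state) - 1, ")")
  invisible(state)
}

living_states <- c("well", "comp_movement", "comp_infection", "comp_fracture")

#' Implantation-phase decision tree
#'
#' OPT patients enter the Markov model in `well`. ICD patients either die
#' post-operatively (within 30 days of implantation) or enter `well`; the
#' entry cost of the ICD arm (device + implantation procedure + post-implant
#' hospitalization) is recorded for cycle 0.
#'
#' @param arm `"OPT"` or `"ICD"`.
#' @param cfg A `study_config`.
#' @return List with `state` (initial state vector) and `entry_cost` (USD).
#' @export
decision_tree_entry <- function(arm, cfg) {
  arm <- match.arg(arm, c("OPT", "ICD"))
  state <- new_state()
  entry_cost <- 0
  if (arm == "OPT") {
    state["well"] <- 1
  } else {
    p_op <- cfg$probabilities$ICD$operative_death$base
    state["dead_operative"] <- p_op
    state["well"] <- 1 - p_op
    entry_cost <- cfg$costs$device_price$base +
      cfg$costs$implant_procedure$base +
      cfg$costs$post_implant_hospitalization$base
  }
  list(state = check_state(state), entry_cost = entry_cost)
}

#' Decompose all-cause mortality into its three causes
#'
#' Non-sudden cardiac death is the residual of trial all-cause mortality
#' after removing sudden cardiac death and the age-specific background
#' non-cardiac probability, floored at zero (floored cases are signalled
#' with a warning, since they mean the background schedule exceeds the
#' trial-implied cardiac risk).
#'
#' @param p_all_cause Annual all-cause mortality from the trial evidence.
#' @param p_scd Annual sudden-cardiac-death probability.
#' @param q_noncardiac Annual background non-cardiac death probability at the
#'   cohort's current age.
#' @return Named numeric: `scd`, `nonsudden_cardiac`, `noncardiac`.
#' @examples
#' decompose_mortality(0.284, 0.108, 0.012) # 0.108, 0.164, 0.012
#' @export
decompose_mortality <- function(p_all_cause, p_scd, q_noncardiac) {
  stopifnot(p_all_cause >= 0, p_all_cause <= 1, p_scd >= 0, p_scd <= 1,
            q_noncardiac >= 0, q_noncardiac <= 1)
  if (p_scd > p_all_cause)
    stop("decompose_mortality: sudden cardiac death exceeds all-cause mortality")
  residual <- p_all_cause - p_scd - q_noncardiac
  if (residual < 0) {
    warning("decompose_mortality: non-sudden cardiac probability floored at 0")
    residual <- 0
  }
  c(scd = p_scd, nonsudden_cardiac = residual, noncardiac = q_noncardiac)
}

#' One annual Markov transition
#'
#' All living states behave identically with respect to death (complication
#' states are transient and return to the well pathway): the cause-specific
#' death probabilities apply first; among survivors in the ICD arm the annual
#' complication probability applies, split between device movement, severe
#' infection and lead fracture/displacement (the residual share); patients
#' entering the infection state die of it within the same cycle with the
#' death-from-infection probability. Dead states are absorbing.
#'
#' @param state Named state vector (fractions summing to 1).
#' @param arm `"OPT"` or `"ICD"`.
#' @param cfg A `study_config`.
#' @param age Current cohort age (used to look up background mortality).
#' @return The next cycle's state vector.
#' @export
cycle_transition <- function(state, arm, cfg, age) {
  arm <- match.arg(arm, c("OPT", "ICD"))
  check_state(state)
  p <- cfg$probabilities[[arm]]
  q_nc <- life_table_q(cfg$life_table, age)
  d <- suppressWarnings(decompose_mortality(p$all_cause$base,
                                            p$sudden_cardiac$base, q_nc))
  p_death <- sum(d)
  if (p_death > 1)
    stop(sprintf(paste0("cycle_transition: total exit probability %.4f > 1 ",
                        "(all_cause %.3f, scd %.3f, q_noncardiac %.3f)"),
                 p_death, p$all_cause$base, p$sudden_cardiac$base, q_nc))
  alive <- sum(state[living_states])
  nxt <- state
  nxt[living_states] <- 0
  nxt["dead_sudden_cardiac"]    <- state["dead_sudden_cardiac"] + alive * d["scd"]
  nxt["dead_nonsudden_cardiac"] <- state["dead_nonsudden_cardiac"] + alive * d["nonsudden_cardiac"]
  nxt["dead_noncardiac"]        <- state["dead_noncardiac"] + alive * d["noncardiac"]
  survivors <- alive * (1 - p_death)
  if (arm == "ICD") {
    pc <- p$complication$base
    pm <- p$movement_given_complication$base
    pi_ <- p$infection_given_complication$base
    pdi <- p$death_given_infection$base
    entering_infection <- survivors * pc * pi_
    nxt["well"]           <- survivors * (1 - pc)
    nxt["comp_movement"]  <- survivors * pc * pm
    nxt["comp_fracture"]  <- survivors * pc * (1 - pm - pi_)
    nxt["comp_infection"] <- entering_infection * (1 - pdi)
    nxt["dead_infection"] <- state["dead_infection"] + entering_infection * pdi
  } else {
    nxt["well"] <- survivors
  }
  check_state(nxt)
}

# Is `cycle` a device replacement cycle? Replacements happen at whole
# multiples of the replacement interval strictly inside the horizon
# (cycle >= 1; the horizon boundary itself is excluded because the trace
# only holds cycles 0 .. horizon-1).
is_replacement_cycle <- function(cycle, cfg) {
  cycle >= 1L && cycle %% cfg$econ$replacement_interval_years == 0L
}

replacement_unit_cost <- function(cfg) {
  pol <- cfg$replacement_cost_policy
  if (is.numeric(pol)) return(pol)
  switch(pol,
         full_device = cfg$costs$device_price$base,
         device_plus_procedure = cfg$costs$device_price$base +
           cfg$costs$implant_procedure$base,
         stop("unknown replacement_cost_policy: ", pol))
}

#' Per-cycle cost and QALY accrual
#'
#' Costs: every living patient accrues the annual OPT management cost;
#' severe-infection occupants accrue the infection management cost plus a new
#' device with implantation and hospitalization; movement/fracture occupants
#' accrue the fracture/displacement cost; at replacement cycles all living
#' ICD patients accrue the device replacement cost. QALYs: well at the well
#' utility, complication states at the complication utility, dead states
#' accrue nothing. Discounting divides by `(1+r)^cycle` (cycle 0
#' undiscounted) at the differential cost/QALY rates.
#'
#' @param state Named state vector at the start of the cycle.
#' @param arm `"OPT"` or `"ICD"`.
#' @param cfg A `study_config`.
#' @param cycle Zero-based cycle index.
#' @return Named numeric: `cost`, `qaly`, `disc_cost`, `disc_qaly`.
#' @export
accrue_cycle <- function(state, arm, cfg, cycle) {
  arm <- match.arg(arm, c("OPT", "ICD"))
  cs <- cfg$costs
  alive <- sum(state[living_states])
  comp <- sum(state[c("comp_movement", "comp_infection", "comp_fracture")])
  cost <- alive * cs$opt_annual$base +
    state[["comp_infection"]] * (cs$major_infection$base + cs$device_price$base +
                                 cs$implant_procedure$base +
                                 cs$post_implant_hospitalization$base) +
    (state[["comp_movement"]] + state[["comp_fracture"]]) * cs$fracture_displacement$base
  if (arm == "ICD" && is_replacement_cycle(cycle, cfg))
    cost <- cost + alive * replacement_unit_cost(cfg)
  qaly <- state[["well"]] * cfg$utilities$well$base +
    comp * cfg$utilities$complication$base
  c(cost = cost, qaly = qaly,
    disc_cost = cost / (1 + cfg$econ$discount_rate_costs)^cycle,
    disc_qaly = qaly / (1 + cfg$econ$discount_rate_qalys)^cycle)
}

#' Run one arm of the model
#'
#' Chains the implantation decision tree and `horizon_years` annual Markov
#' cycles, accruing discounted costs and QALYs per cycle. The entry cost of
#' the ICD arm is charged (undiscounted) at cycle 0.
#'
#' @param arm `"OPT"` or `"ICD"`.
#' @param cfg A `study_config`.
#' @param keep_trace If `FALSE`, skip building the per-cycle trace (totals
#'   only); used by the Monte Carlo loop where only totals are needed.
#' @return An object of class `arm_result`: list with `arm`,
#'   `total_discounted_cost`, `total_discounted_qaly`, `total_cost`,
#'   `total_qaly`, and `trace` (one row per cycle: cycle, age, the nine state
#'   fractions, undiscounted and discounted cost and QALY; `NULL` when
#'   `keep_trace = FALSE`).
#' @examples
#' res <- run_arm("OPT", fixture_config("base_case"))
#' res$total_discounted_qaly
#' @export
run_arm <- function(arm, cfg, keep_trace = TRUE) {
  arm <- match.arg(arm, c("OPT", "ICD"))
  stopifnot(inherits(cfg, "study_config"))
  if (isTRUE(cfg$meta$requires_user_input))
    stop("this configuration is a subgroup stub with placeholder (NA) ",
         "probabilities; substitute real values before running")
  cfg <- extend_life_table(cfg)
  horizon <- cfg$econ$horizon_years
  entry <- decision_tree_entry(arm, cfg)
  state <- entry$state
  acc_names <- c("cost", "qaly", "disc_cost", "disc_qaly")
  m <- if (keep_trace)
    matrix(NA_real_, horizon, 2L + 9L + 4L,
           dimnames = list(NULL, c("cycle", "age", state_names(), acc_names)))
  totals <- c(cost = 0, qaly = 0, disc_cost = 0, disc_qaly = 0)
  for (cycle in 0:(horizon - 1L)) {
    acc <- accrue_cycle(state, arm, cfg, cycle)
    if (cycle == 0L) {
      acc[c("cost", "disc_cost")] <- acc[c("cost", "disc_cost")] + entry$entry_cost
    }
    totals <- totals + acc
    if (keep_trace)
      m[cycle + 1L, ] <- c(cycle, cfg$econ$start_age + cycle, state, acc)
    state <- cycle_transition(state, arm, cfg,
                              age = cfg$econ$start_age + cycle)
  }
  structure(list(arm = arm,
                 total_discounted_cost = totals[["disc_cost"]],
                 total_discounted_qaly = totals[["disc_qaly"]],
                 total_cost = totals[["cost"]],
                 total_qaly = totals[["qaly"]],
                 trace = if (keep_trace) as.data.frame(m)),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm over %d cycles: discounted cost USD %.2f, discounted QALY %.4f\n",
              x$arm, nrow(x$trace), x$total_discounted_cost,
              x$total_discounted_qaly))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle with the fixed column order: cycle, age, the nine state
#' fractions, undiscounted and discounted cost and QALY.
#'
#' @param result An `arm_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(result, path) {
  stopifnot(inherits(result, "arm_result"))
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
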