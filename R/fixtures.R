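# Packaged study configurations: the published base case and its named
# scenario variants, constructed in code so every downstream stage is
# testable without external data.

#' Packaged study configurations
#'
#' Returns the base-case parameter set of the evaluation (all published
#' values: beta counts for probabilities and the well utility, min-max
#' ranges for costs in 2017 USD) or a named single-setting variant of it.
#'
#' Scenarios:
#' \describe{
#'   \item{base_case}{10-year horizon, 5-year replacement, published values.}
#'   \item{five_year}{horizon 5 years, all else base case.}
#'   \item{twenty_year}{horizon 20 years.}
#'   \item{replacement_7y}{device replaced every 7 years.}
#'   \item{ischemic_stub, nonischemic_stub}{base case with the arm mortality
#'     probabilities blanked (`NA`): the subgroup inputs were never published,
#'     so these configurations refuse to run until the user substitutes
#'     values (see [scenario()]).}
#' }
#'
#' The background non-cardiac mortality table is the synthetic Gompertz
#' schedule `calibrate_life_table(0.012, 8, start_age, horizon)`: a
#' 60-year-old's annual background risk of about 1.2%, with the hazard
#' doubling every 8 years.
#'
#' @param scenario One of the names above.
#' @return A validated `study_config` (stub scenarios carry
#'   `meta$requires_user_input = TRUE`).
#' @examples
#' cfg <- fixture_config("base_case")
#' cfg$costs$device_price$base # 7259.46
#' @export
fixture_config <- function(scenario = c("base_case", "five_year", "twenty_year",
                                        "replacement_7y", "ischemic_stub",
                                        "nonischemic_stub")) {
  scenario <- match.arg(scenario)
  horizon <- switch(scenario, five_year = 5L, twenty_year = 20L, 10L)
  repl <- if (scenario == "replacement_7y") 7L else 5L
  econ <- econ_settings(horizon_years = horizon,
                        replacement_interval_years = repl)
  lt_spec <- list(q_start = 0.012, doubling_time_years = 8)
  lt <- calibrate_life_table(lt_spec$q_start, lt_spec$doubling_time_years,
                             econ$start_age, horizon)
  probs <- list(
    OPT = list(
      operative_death = prob_param(0),
      all_cause       = prob_param(0.284, beta_count(604, 1522)),
      sudden_cardiac  = prob_param(0.108, beta_count(317, 2605))
    ),
    ICD = list(
      operative_death = prob_param(0, beta_count(0, 2774)),
      all_cause       = prob_param(0.178, beta_count(385, 1790)),
      sudden_cardiac  = prob_param(0.037, beta_count(110, 2825)),
      complication    = prob_param(0.062, beta_count(169, 2554)),
      movement_given_complication  = prob_param(0.5, beta_count(16, 16)),
      infection_given_complication = prob_param(0.2, beta_count(10, 40)),
      death_given_infection        = prob_param(0.21, beta_from_moments(0.2098, 0.1275))
    )
  )
  utilities <- list(
    well         = prob_param(0.845, beta_count(6.164, 1.131)),
    complication = prob_param(0.75)
  )
  costs <- list(
    opt_annual                   = cost_range(313.04, 282.08, 343.95),
    device_price                 = cost_range(7259.46, 6539.44, 7793.12),
    implant_procedure            = cost_range(300.28, 289.80, 337.59),
    post_implant_hospitalization = cost_range(73.39, 70.11, 84.01),
    major_infection              = cost_range(194.17, 184.57, 223.73),
    fracture_displacement        = cost_range(187.83, 180.60, 213.83)
  )
  meta <- list(scenario = scenario)
  if (scenario %in% c("ischemic_stub", "nonischemic_stub")) {
    # subgroup inputs were never published: blank the mortality rows so the
    # configuration cannot silently run with general-population values
    for (arm in c("OPT", "ICD")) {
      probs[[arm]]$all_cause$base <- NA_real_
      probs[[arm]]$all_cause$dist <- NULL
      probs[[arm]]$sudden_cardiac$base <- NA_real_
      probs[[arm]]$sudden_cardiac$dist <- NULL
    }
    meta$requires_user_input <- TRUE
  }
  study_config(probs, utilities, costs, econ, lt, life_table_spec = lt_spec,
               meta = meta)
}

# Ensure the life table spans the configured horizon, regenerating it from
# its stored Gompertz spec when a scenario override lengthens the run.
extend_life_table <- function(cfg) {
  need <- cfg$econ$start_age + seq_len(cfg$econ$horizon_years) - 1L
  if (all(need %in% cfg$life_table$age)) return(cfg)
  if (is.null(cfg$life_table_spec))
    stop("life table does not cover the horizon and has no generator spec to extend it")
  cfg$life_table <- calibrate_life_table(cfg$life_table_spec$q_start,
                                         cfg$life_table_spec$doubling_time_years,
                                         cfg$econ$start_age,
                                         cfg$econ$horizon_years)
  cfg
}
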