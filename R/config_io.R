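# YAML serialization of study configurations. One documented schema; the
# writer emits keys in a fixed order with full float precision so that
# write -> load -> write is byte-stable.

prob_to_list <- function(p) {
  out <- list(base = p$base)
  if (!is.null(p$dist)) { out$alpha <- p$dist$alpha; out$beta <- p$dist$beta }
  out
}

prob_from_list <- function(l, where) {
  if (is.null(l$base)) stop("config: missing 'base' in ", where)
  dist <- NULL
  if (!is.null(l$alpha) || !is.null(l$beta)) {
    if (is.null(l$alpha) || is.null(l$beta))
      stop("config: ", where, " must give both alpha and beta or neither")
    dist <- beta_count(l$alpha, l$beta)
  }
  prob_param(if (is.null(l$base) || is.na(l$base)) NA_real_ else l$base, dist)
}

cost_from_list <- function(l, where) {
  for (f in c("base", "min", "max"))
    if (is.null(l[[f]])) stop("config: missing '", f, "' in cost ", where)
  cost_range(l$base, l$min, l$max)
}

config_to_list <- function(cfg) {
  arm_order <- list(
    OPT = c("operative_death", "all_cause", "sudden_cardiac"),
    ICD = c("operative_death", "all_cause", "sudden_cardiac", "complication",
            "movement_given_complication", "infection_given_complication",
            "death_given_infection"))
  probs <- lapply(names(arm_order), function(arm) {
    lapply(cfg$probabilities[[arm]][arm_order[[arm]]], prob_to_list)
  })
  names(probs) <- names(arm_order)
  cost_order <- c("opt_annual", "device_price", "implant_procedure",
                  "post_implant_hospitalization", "major_infection",
                  "fracture_displacement")
  out <- list(
    schema = "icdcea-config-1",
    economics = unclass(cfg$econ),
    probabilities = probs,
    utilities = lapply(cfg$utilities[c("well", "complication")], prob_to_list),
    costs = lapply(cfg$costs[cost_order], unclass),
    replacement_cost_policy = cfg$replacement_cost_policy)
  if (!is.null(cfg$life_table_spec)) {
    out$life_table <- list(q_start = cfg$life_table_spec$q_start,
                           doubling_time_years = cfg$life_table_spec$doubling_time_years)
  } else {
    out$life_table <- list(age = as.list(cfg$life_table$age),
                           q = as.list(cfg$life_table$q))
  }
  if (length(cfg$meta)) out$meta <- cfg$meta
  out
}

#' Write a study configuration to YAML
#'
#' @param cfg A `study_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  txt <- yaml::as.yaml(config_to_list(cfg), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}

#' Load and validate a study configuration from YAML
#'
#' Reads the documented schema (see the packaged file
#' `system.file("extdata", "table1_base_case.yaml", package = "icdcea")`),
#' rebuilds the life table from its Gompertz spec when one is stored, and
#' runs [validate_config()]. Missing fields raise an error naming the field.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  l <- yaml::read_yaml(path)
  for (f in c("economics", "probabilities", "utilities", "costs", "life_table"))
    if (is.null(l[[f]])) stop("config: missing top-level field '", f, "'")
  e <- l$economics
  for (f in c("horizon_years", "discount_rate_costs", "discount_rate_qalys",
              "start_age", "replacement_interval_years", "wtp_low", "wtp_high"))
    if (is.null(e[[f]])) stop("config: missing economics field '", f, "'")
  econ <- econ_settings(e$horizon_years, e$discount_rate_costs,
                        e$discount_rate_qalys, e$start_age,
                        e$replacement_interval_years, e$wtp_low, e$wtp_high,
                        e$exchange_rate_cop_per_usd %||% 2951.32)
  probs <- lapply(c(OPT = "OPT", ICD = "ICD"), function(arm) {
    pa <- l$probabilities[[arm]]
    if (is.null(pa)) stop("config: missing probabilities for arm ", arm)
    lapply(stats::setNames(names(pa), names(pa)), function(nm)
      prob_from_list(pa[[nm]], paste0("probabilities.", arm, ".", nm)))
  })
  utilities <- lapply(stats::setNames(names(l$utilities), names(l$utilities)),
                      function(nm) prob_from_list(l$utilities[[nm]],
                                                  paste0("utilities.", nm)))
  costs <- lapply(stats::setNames(names(l$costs), names(l$costs)),
                  function(nm) cost_from_list(l$costs[[nm]], nm))
  lt_spec <- NULL
  if (!is.null(l$life_table$q_start)) {
    lt_spec <- list(q_start = l$life_table$q_start,
                    doubling_time_years = l$life_table$doubling_time_years)
    lt <- calibrate_life_table(lt_spec$q_start, lt_spec$doubling_time_years,
                               econ$start_age, econ$horizon_years)
  } else {
    lt <- structure(data.frame(age = as.integer(unlist(l$life_table$age)),
                               q = as.numeric(unlist(l$life_table$q))),
                    class = c("life_table", "data.frame"))
  }
  study_config(probs, utilities, costs, econ, lt, life_table_spec = lt_spec,
               replacement_cost_policy = l$replacement_cost_policy %||% "full_device",
               meta = l$meta %||% list())
}

#' Path to the packaged base-case configuration
#'
#' @return File path of the YAML file reproducing every published base-case
#'   value.
#' @export
base_case_config_path <- function() {
  system.file("extdata", "table1_base_case.yaml", package = "icdcea",
              mustWork = TRUE)
}
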