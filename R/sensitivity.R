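# Deterministic sensitivity analysis: one-way parameter sweeps, the tornado
# ranking, and named scenario runs.

#' Addressable parameter names
#'
#' Flat dotted paths used by [set_param()], [one_way()] and [scenario()]:
#' `cost.<name>` (base value of a cost), `prob.<ARM>.<name>` (base value of a
#' probability), `utility.well` / `utility.complication`, and
#' `econ.<setting>` (e.g. `econ.horizon_years`,
#' `econ.replacement_interval_years`).
#'
#' @param cfg A `study_config`.
#' @return Character vector of every addressable path in `cfg`.
#' @export
param_names <- function(cfg) {
  c(paste0("cost.", names(cfg$costs)),
    unlist(lapply(c("OPT", "ICD"), function(a)
      paste0("prob.", a, ".", names(cfg$probabilities[[a]])))),
    paste0("utility.", names(cfg$utilities)),
    paste0("econ.", names(cfg$econ)))
}

#' Set one addressable parameter
#'
#' @param cfg A `study_config`.
#' @param name Dotted path from [param_names()].
#' @param value New value (base value for costs/probabilities/utilities).
#' @return The modified, re-validated `study_config`.
#' @export
set_param <- function(cfg, name, value) {
  stopifnot(inherits(cfg, "study_config"), is.character(name))
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "cost" && length(parts) == 2 && parts[2] %in% names(cfg$costs)) {
    old <- cfg$costs[[parts[2]]]
    cfg$costs[[parts[2]]] <- cost_range(value, min(old$min, value),
                                        max(old$max, value))
  } else if (kind == "prob" && length(parts) == 3 &&
             parts[2] %in% c("OPT", "ICD") &&
             parts[3] %in% names(cfg$probabilities[[parts[2]]])) {
    cfg$probabilities[[parts[2]]][[parts[3]]]$base <- value
  } else if (kind == "utility" && length(parts) == 2 &&
             parts[2] %in% names(cfg$utilities)) {
    cfg$utilities[[parts[2]]]$base <- value
    # a well utility swept below the complication utility drags the latter
    # down with it (complications can never be preferred to the well state)
    if (parts[2] == "well")
      cfg$utilities$complication$base <-
        min(cfg$utilities$complication$base, value)
  } else if (kind == "econ" && length(parts) == 2 &&
             parts[2] %in% names(cfg$econ)) {
    cfg$econ[[parts[2]]] <- if (parts[2] %in%
        c("horizon_years", "start_age", "replacement_interval_years"))
      as.integer(value) else value
    cfg <- extend_life_table(cfg)
  } else {
    stop("set_param: unknown parameter '", name, "'")
  }
  validate_config(cfg)
}

get_param <- function(cfg, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(parts[1],
         cost = cfg$costs[[parts[2]]]$base,
         prob = cfg$probabilities[[parts[2]]][[parts[3]]]$base,
         utility = cfg$utilities[[parts[2]]]$base,
         econ = cfg$econ[[parts[2]]],
         stop("get_param: unknown parameter '", name, "'"))
}

# Default sweep range for a parameter: published min-max for costs, central
# 95% beta interval for probabilities/utilities with a distribution,
# otherwise NULL (not sweepable by default).
default_range <- function(cfg, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "cost") {
    cr <- cfg$costs[[parts[2]]]
    return(c(cr$min, cr$max))
  }
  p <- switch(parts[1],
              prob = cfg$probabilities[[parts[2]]][[parts[3]]],
              utility = cfg$utilities[[parts[2]]],
              return(NULL))
  if (is.null(p$dist)) return(NULL)
  beta_interval(p$dist, 0.95)
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs both arms with the parameter at each bound (all else at its base
#' value) and records the two ICERs.
#'
#' @param cfg A `study_config`.
#' @param parameter Dotted path from [param_names()].
#' @param low,high Bounds; defaults from the published min-max (costs) or
#'   central 95% beta interval (probabilities/utilities).
#' @return A one-row data frame of class `tornado_entry`: parameter, low,
#'   high, icer_low, icer_high, span = |icer_high - icer_low|.
#' @export
one_way <- function(cfg, parameter, low = NULL, high = NULL) {
  if (!parameter %in% param_names(cfg))
    stop("one_way: unknown parameter '", parameter, "'")
  rng <- default_range(cfg, parameter)
  if (is.null(low)) low <- rng[1]
  if (is.null(high)) high <- rng[2]
  if (is.null(low) || is.null(high))
    stop("one_way: no default range for '", parameter, "'; give low and high")
  if (low > high) stop("one_way: low > high for '", parameter, "'")
  # sweeping a parameter away from its distribution mean is intentional
  # here, so the config-consistency warning is silenced
  i_low <- run_comparison(suppressWarnings(set_param(cfg, parameter, low)), keep_trace = FALSE)$ce$icer
  i_high <- run_comparison(suppressWarnings(set_param(cfg, parameter, high)), keep_trace = FALSE)$ce$icer
  structure(data.frame(parameter = parameter, low = low, high = high,
                       icer_low = i_low, icer_high = i_high,
                       span = abs(i_high - i_low)),
            class = c("tornado_entry", "data.frame"))
}

#' Tornado analysis
#'
#' One-way sweeps over a set of parameters, sorted by the width of the ICER
#' interval each induces (descending), for the classic tornado diagram.
#'
#' @param cfg A `study_config`.
#' @param parameters Character vector of dotted paths; default: every cost,
#'   every probability with a sampling distribution (except the degenerate
#'   operative death), and the well utility.
#' @param ranges Optional named list of `c(low, high)` overrides.
#' @return A `tornado_entry` data frame, one row per parameter, sorted by
#'   span descending.
#' @export
tornado <- function(cfg, parameters = NULL, ranges = list()) {
  if (is.null(parameters)) {
    parameters <- c(paste0("cost.", names(cfg$costs)),
                    "prob.OPT.all_cause", "prob.OPT.sudden_cardiac",
                    "prob.ICD.all_cause", "prob.ICD.sudden_cardiac",
                    "prob.ICD.complication",
                    "prob.ICD.movement_given_complication",
                    "prob.ICD.infection_given_complication",
                    "prob.ICD.death_given_infection",
                    "utility.well")
  }
  rows <- lapply(parameters, function(pm) {
    r <- ranges[[pm]]
    if (is.null(r)) one_way(cfg, pm) else one_way(cfg, pm, r[1], r[2])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado_entry", "data.frame"))
}

#' Export a tornado table as CSV
#'
#' @param tor A `tornado_entry` data frame from [tornado()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_tornado <- function(tor, path) {
  utils::write.csv(tor, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a named or ad-hoc scenario
#'
#' Applies parameter overrides to a configuration, runs both arms, and
#' returns the incremental comparison. Named scenarios from
#' [fixture_config()] (horizon 5/20, 7-year replacement, subgroup stubs) can
#' be run directly by passing their configuration here with no overrides.
#'
#' @param cfg A `study_config`.
#' @param overrides Named list mapping dotted parameter paths to values,
#'   e.g. `list("econ.horizon_years" = 20)`.
#' @return A list as from [run_comparison()].
#' @export
scenario <- function(cfg, overrides = list()) {
  for (nm in names(overrides)) cfg <- set_param(cfg, nm, overrides[[nm]])
  run_comparison(cfg)
}
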