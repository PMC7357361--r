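# Parameter primitives: beta pseudo-count distributions for probabilities and
# utilities, uniform min-max ranges for costs, and the study configuration
# object that aggregates them.

#' Beta pseudo-count distribution
#'
#' A probability (or utility) parameter expressed as a beta distribution with
#' pseudo-event count `alpha` and pseudo-non-event count `beta`. `alpha = 0`
#' is allowed and treated as a degenerate point mass at zero (used for
#' operative death, where no events were observed).
#'
#' @param alpha Non-negative pseudo-event count.
#' @param beta Non-negative pseudo-non-event count.
#' @return An object of class `beta_count`.
#' @examples
#' beta_mean(beta_count(604, 1522)) # 0.284
#' @export
beta_count <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L)
  if (alpha < 0 || beta < 0) stop("beta_count: alpha and beta must be >= 0")
  if (alpha + beta <= 0) stop("beta_count: alpha + beta must be > 0")
  structure(list(alpha = alpha, beta = beta), class = "beta_count")
}

#' @export
print.beta_count <- function(x, ...) {
  cat(sprintf("Beta(alpha = %g, beta = %g), mean = %.5f\n",
              x$alpha, x$beta, beta_mean(x)))
  invisible(x)
}

#' Mean of a beta pseudo-count distribution
#'
#' @param b A [beta_count()] object.
#' @return `alpha / (alpha + beta)`.
#' @export
beta_mean <- function(b) {
  stopifnot(inherits(b, "beta_count"))
  b$alpha / (b$alpha + b$beta)
}

#' Standard deviation of a beta pseudo-count distribution
#'
#' @param b A [beta_count()] object.
#' @return The beta standard deviation; 0 for the degenerate `alpha = 0` case.
#' @export
beta_sd <- function(b) {
  stopifnot(inherits(b, "beta_count"))
  a <- b$alpha; bb <- b$beta; n <- a + bb
  sqrt(a * bb / (n^2 * (n + 1)))
}

#' Construct a beta distribution from its first two moments
#'
#' Method-of-moments inversion: `nu = mean (1 - mean) / sd^2 - 1`,
#' `alpha = mean nu`, `beta = (1 - mean) nu`. Used for parameters reported
#' only as an estimate with a standard deviation (death from device
#' infection).
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return A [beta_count()] object.
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L)
  if (mean <= 0 || mean >= 1) stop("beta_from_moments: mean must be in (0, 1)")
  if (sd <= 0) stop("beta_from_moments: sd must be > 0")
  if (sd^2 >= mean * (1 - mean))
    stop("beta_from_moments: infeasible moments, sd^2 must be < mean*(1-mean)")
  nu <- mean * (1 - mean) / sd^2 - 1
  beta_count(mean * nu, (1 - mean) * nu)
}

#' Central interval of a beta pseudo-count distribution
#'
#' Equal-tailed `level` interval via [stats::qbeta()]; degenerate
#' distributions return a zero-width interval at their point mass.
#'
#' @param b A [beta_count()] object.
#' @param level Coverage, default 0.95.
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
beta_interval <- function(b, level = 0.95) {
  stopifnot(inherits(b, "beta_count"))
  if (b$alpha == 0) return(c(0, 0))
  if (b$beta == 0) return(c(1, 1))
  p <- (1 - level) / 2
  stats::qbeta(c(p, 1 - p), b$alpha, b$beta)
}

#' Cost parameter with uniform sampling range
#'
#' @param base Base-case cost in USD.
#' @param min,max Uniform sampling bounds in USD, `min <= base <= max`.
#' @return An object of class `cost_range`.
#' @export
cost_range <- function(base, min, max) {
  stopifnot(is.numeric(base), is.numeric(min), is.numeric(max))
  if (min < 0 || base < 0 || max < 0) stop("cost_range: costs must be >= 0")
  if (min > base || base > max)
    stop(sprintf("cost_range: need min <= base <= max, got %g, %g, %g",
                 min, base, max))
  structure(list(base = base, min = min, max = max), class = "cost_range")
}

#' @export
print.cost_range <- function(x, ...) {
  cat(sprintf("USD %.2f [%.2f - %.2f]\n", x$base, x$min, x$max))
  invisible(x)
}

# A probability parameter: base-case value plus (optionally) its beta source.
prob_param <- function(base, dist = NULL) {
  stopifnot(is.numeric(base), base >= 0, base <= 1)
  if (!is.null(dist)) stopifnot(inherits(dist, "beta_count"))
  list(base = base, dist = dist)
}

#' Economic settings of the evaluation
#'
#' @param horizon_years Markov horizon in annual cycles (>= 1).
#' @param discount_rate_costs Annual discount rate for costs.
#' @param discount_rate_qalys Annual discount rate for QALYs.
#' @param start_age Cohort entry age in years.
#' @param replacement_interval_years Device replacement interval (generator
#'   battery life), in years.
#' @param wtp_low,wtp_high Willingness-to-pay thresholds in USD/QALY
#'   (1x and 3x GDP per capita).
#' @param exchange_rate_cop_per_usd COP per USD, retained as metadata only.
#' @return An object of class `econ_settings`.
#' @export
econ_settings <- function(horizon_years = 10L,
                          discount_rate_costs = 0.03,
                          discount_rate_qalys = 0.035,
                          start_age = 60L,
                          replacement_interval_years = 5L,
                          wtp_low = 6308,
                          wtp_high = 19139,
                          exchange_rate_cop_per_usd = 2951.32) {
  horizon_years <- as.integer(horizon_years)
  if (horizon_years < 1L) stop("econ_settings: horizon_years must be >= 1")
  if (discount_rate_costs < 0 || discount_rate_costs >= 1 ||
      discount_rate_qalys < 0 || discount_rate_qalys >= 1)
    stop("econ_settings: discount rates must be in [0, 1)")
  if (replacement_interval_years < 1L)
    stop("econ_settings: replacement_interval_years must be >= 1")
  if (wtp_low > wtp_high) stop("econ_settings: wtp_low must be <= wtp_high")
  structure(list(horizon_years = horizon_years,
                 discount_rate_costs = discount_rate_costs,
                 discount_rate_qalys = discount_rate_qalys,
                 start_age = as.integer(start_age),
                 replacement_interval_years = as.integer(replacement_interval_years),
                 wtp_low = wtp_low, wtp_high = wtp_high,
                 exchange_rate_cop_per_usd = exchange_rate_cop_per_usd),
            class = "econ_settings")
}

#' Assemble a study configuration
#'
#' The single source of truth for a model run: per-arm transition
#' probabilities (with their beta sources), utility weights, cost ranges,
#' economic settings and the background non-cardiac mortality life table.
#' Most users will start from [fixture_config()] or [load_config()] rather
#' than calling this directly.
#'
#' @param probabilities Named list with elements `OPT` and `ICD`, each a named
#'   list of probability parameters (`base` plus optional `dist`
#'   [beta_count()]): `operative_death`, `all_cause`, `sudden_cardiac`, and
#'   for the ICD arm `complication`, `movement_given_complication`,
#'   `infection_given_complication`, `death_given_infection`.
#' @param utilities Named list with `well` and `complication` probability
#'   parameters.
#' @param costs Named list of [cost_range()]: `opt_annual`, `device_price`,
#'   `implant_procedure`, `post_implant_hospitalization`, `major_infection`,
#'   `fracture_displacement`.
#' @param econ An [econ_settings()] object.
#' @param life_table A life table from [gompertz_life_table()] or
#'   [calibrate_life_table()]; regenerated automatically when the horizon is
#'   extended if `life_table_spec` is present.
#' @param life_table_spec Optional list `(q_start, doubling_time_years)` used
#'   to regenerate the table for longer horizons.
#' @param replacement_cost_policy `"full_device"`, `"device_plus_procedure"`,
#'   or a numeric custom USD amount.
#' @param meta Optional named list of free-form metadata (scenario label,
#'   placeholder flags).
#' @return An object of class `study_config`.
#' @export
study_config <- function(probabilities, utilities, costs, econ, life_table,
                         life_table_spec = NULL,
                         replacement_cost_policy = "full_device",
                         meta = list()) {
  cfg <- structure(list(probabilities = probabilities, utilities = utilities,
                        costs = costs, econ = econ, life_table = life_table,
                        life_table_spec = life_table_spec,
                        replacement_cost_policy = replacement_cost_policy,
                        meta = meta),
                   class = "study_config")
  validate_config(cfg)
}

#' Validate a study configuration
#'
#' Checks all structural invariants (probabilities in \[0, 1\], SCD not
#' exceeding all-cause mortality, complication shares summing to at most 1,
#' cost ranges ordered, life-table coverage of the horizon). Base-case
#' probabilities that disagree with their beta-count mean by more than 0.002
#' raise a warning, not an error.
#'
#' @param cfg A `study_config`.
#' @return `cfg`, invisibly usable, after passing all checks.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  req_cost <- c("opt_annual", "device_price", "implant_procedure",
                "post_implant_hospitalization", "major_infection",
                "fracture_displacement")
  missing_c <- setdiff(req_cost, names(cfg$costs))
  if (length(missing_c))
    stop("study_config: missing cost field(s): ", paste(missing_c, collapse = ", "))
  for (nm in req_cost) {
    cr <- cfg$costs[[nm]]
    if (!inherits(cr, "cost_range")) stop("cost '", nm, "' is not a cost_range")
  }
  for (arm in c("OPT", "ICD")) {
    p <- cfg$probabilities[[arm]]
    if (is.null(p)) stop("study_config: missing probabilities for arm ", arm)
    req_p <- c("operative_death", "all_cause", "sudden_cardiac")
    if (arm == "ICD")
      req_p <- c(req_p, "complication", "movement_given_complication",
                 "infection_given_complication", "death_given_infection")
    missing_p <- setdiff(req_p, names(p))
    if (length(missing_p))
      stop("study_config: arm ", arm, " missing probability field(s): ",
           paste(missing_p, collapse = ", "))
    for (nm in names(p)) {
      b <- p[[nm]]$base
      if (is.na(b)) next  # placeholder (subgroup stub); flagged via meta
      if (b < 0 || b > 1)
        stop("probability ", arm, "$", nm, " outside [0, 1]: ", b)
      d <- p[[nm]]$dist
      if (!is.null(d) && abs(b - beta_mean(d)) > 0.002)
        warning(sprintf(
          "probability %s$%s: base %.4f differs from beta mean %.4f by > 0.002",
          arm, nm, b, beta_mean(d)))
    }
    if (!is.na(p$sudden_cardiac$base) && !is.na(p$all_cause$base) &&
        p$sudden_cardiac$base > p$all_cause$base)
      stop("arm ", arm, ": sudden cardiac death probability exceeds all-cause mortality")
    if (arm == "ICD") {
      mv <- p$movement_given_complication$base
      inf <- p$infection_given_complication$base
      if (!is.na(mv) && !is.na(inf) && mv + inf > 1)
        stop("ICD: movement + infection shares of complications exceed 1")
    }
  }
  uw <- cfg$utilities$well$base; ucp <- cfg$utilities$complication$base
  if (ucp > uw) stop("utility: complication utility exceeds well utility")
  pol <- cfg$replacement_cost_policy
  if (!(is.numeric(pol) ||
        (is.character(pol) && pol %in% c("full_device", "device_plus_procedure"))))
    stop("replacement_cost_policy must be 'full_device', 'device_plus_procedure' or a numeric USD amount")
  lt <- cfg$life_table
  if (!is.data.frame(lt) || !all(c("age", "q") %in% names(lt)))
    stop("life_table must be a data frame with columns age and q")
  need <- cfg$econ$start_age + seq_len(cfg$econ$horizon_years) - 1L
  if (!all(need %in% lt$age))
    stop("life_table does not cover ages ", min(need), "-", max(need))
  if (any(lt$q < 0 | lt$q > 1)) stop("life_table q outside [0, 1]")
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration (", x$meta$scenario %||% "unnamed", ")\n", sep = "")
  cat(sprintf("  horizon %d y, start age %d, discount %g%%/%g%% (costs/QALYs), replacement every %d y\n",
              x$econ$horizon_years, x$econ$start_age,
              100 * x$econ$discount_rate_costs, 100 * x$econ$discount_rate_qalys,
              x$econ$replacement_interval_years))
  cat(sprintf("  OPT all-cause %.3f, SCD %.3f | ICD all-cause %.3f, SCD %.3f, complication %.3f\n",
              x$probabilities$OPT$all_cause$base, x$probabilities$OPT$sudden_cardiac$base,
              x$probabilities$ICD$all_cause$base, x$probabilities$ICD$sudden_cardiac$base,
              x$probabilities$ICD$complication$base))
  cat(sprintf("  device USD %.2f, OPT annual USD %.2f, utilities %.3f/%.2f\n",
              x$costs$device_price$base, x$costs$opt_annual$base,
              x$utilities$well$base, x$utilities$complication$base))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive ICD-arm probabilities from the OPT arm via relative risks
#'
#' Returns a copy of `cfg` whose ICD-arm all-cause and sudden-cardiac-death
#' base probabilities are the OPT-arm values multiplied by the given relative
#' risks (the trial meta-analysis reports RR 0.73 for all-cause mortality and
#' 0.40 for sudden cardiac death). The packaged base case instead carries the
#' pooled count rates; see the methods vignette for why both readings exist.
#'
#' @param cfg A `study_config`.
#' @param rr_all_cause,rr_scd Relative risks applied to the OPT-arm base
#'   probabilities.
#' @return A modified `study_config` (beta-count sources for the derived
#'   entries are dropped, since the product of a beta and a constant is not a
#'   beta with printable counts).
#' @export
apply_relative_risks <- function(cfg, rr_all_cause = 0.73, rr_scd = 0.40) {
  stopifnot(inherits(cfg, "study_config"), rr_all_cause >= 0, rr_scd >= 0)
  cfg$probabilities$ICD$all_cause <-
    prob_param(min(1, rr_all_cause * cfg$probabilities$OPT$all_cause$base))
  cfg$probabilities$ICD$sudden_cardiac <-
    prob_param(min(1, rr_scd * cfg$probabilities$OPT$sudden_cardiac$base))
  cfg$meta$icd_probabilities <- "rr_derived"
  validate_config(cfg)
}
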