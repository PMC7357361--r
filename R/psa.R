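# Probabilistic sensitivity analysis: joint sampling of all uncertain
# parameters (beta for probabilities and the well utility, uniform for
# costs), Monte Carlo propagation through both arms, and the
# cost-effectiveness acceptability curve.

draw_prob <- function(p) {
  if (is.null(p$dist)) return(p$base)            # no distribution: fixed
  if (p$dist$alpha == 0) return(0)               # degenerate point mass
  stats::rbeta(1, p$dist$alpha, p$dist$beta)
}

#' Draw one joint parameter sample
#'
#' Every probability and the well utility with a beta source is drawn from
#' its beta distribution (the degenerate `alpha = 0` operative-death entry is
#' a point mass at 0); every cost is drawn uniformly on its min-max range.
#' Draws are independent across parameters and across the two arms. Two
#' structural guards keep sampled configurations valid: sudden cardiac death
#' is capped at the sampled all-cause mortality, and the movement/infection
#' complication shares are rescaled proportionally in the rare draws where
#' they sum above 1.
#'
#' @param cfg A `study_config` (the distribution source).
#' @return A `study_config` whose base values are the sampled ones; sampling
#'   distributions are retained untouched.
#' @export
sample_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  s <- cfg
  for (arm in c("OPT", "ICD")) {
    for (nm in names(s$probabilities[[arm]])) {
      s$probabilities[[arm]][[nm]]$base <- draw_prob(cfg$probabilities[[arm]][[nm]])
    }
    p <- s$probabilities[[arm]]
    if (p$sudden_cardiac$base > p$all_cause$base)
      s$probabilities[[arm]]$sudden_cardiac$base <- p$all_cause$base
  }
  pm <- s$probabilities$ICD$movement_given_complication$base
  pi_ <- s$probabilities$ICD$infection_given_complication$base
  if (pm + pi_ > 1) {
    s$probabilities$ICD$movement_given_complication$base <- pm / (pm + pi_)
    s$probabilities$ICD$infection_given_complication$base <- pi_ / (pm + pi_)
  }
  uw <- draw_prob(cfg$utilities$well)
  s$utilities$well$base <- uw
  s$utilities$complication$base <- min(cfg$utilities$complication$base, uw)
  for (nm in names(s$costs)) {
    cr <- cfg$costs[[nm]]
    v <- stats::runif(1, cr$min, cr$max)
    s$costs[[nm]] <- cost_range(v, cr$min, cr$max)
  }
  s
}

#' Collapse all sampling distributions to their means
#'
#' Replaces every base value by the mean of its sampling distribution (beta
#' mean for probabilities/utilities, range midpoint for costs). A PSA whose
#' distributions are collapsed this way reproduces the deterministic run of
#' the collapsed configuration exactly.
#'
#' @param cfg A `study_config`.
#' @return The collapsed `study_config`.
#' @export
collapse_to_means <- function(cfg) {
  s <- cfg
  for (arm in c("OPT", "ICD"))
    for (nm in names(s$probabilities[[arm]])) {
      d <- cfg$probabilities[[arm]][[nm]]$dist
      if (!is.null(d))
        s$probabilities[[arm]][[nm]]$base <- if (d$alpha == 0) 0 else beta_mean(d)
    }
  if (!is.null(cfg$utilities$well$dist))
    s$utilities$well$base <- beta_mean(cfg$utilities$well$dist)
  for (nm in names(s$costs)) {
    cr <- cfg$costs[[nm]]
    s$costs[[nm]] <- cost_range((cr$min + cr$max) / 2, cr$min, cr$max)
  }
  validate_config(s)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each of `n` draws, samples all uncertain parameters jointly, runs both
#' arms, and records the incremental cost and QALY. The deterministic base
#' case is not altered.
#'
#' @param cfg A `study_config`.
#' @param n Number of Monte Carlo draws (>= 1); the study design uses 10,000.
#' @param seed Integer RNG seed; required so runs are reproducible.
#' @param collapse If `TRUE`, skip sampling and use [collapse_to_means()]
#'   values for every draw (degenerate PSA, used for verification).
#' @return An object of class `psa_result`: data frame with columns `draw`,
#'   the sampled headline parameters (`p_opt_all_cause`, `p_icd_all_cause`,
#'   `u_well`, `device_price`), `delta_cost`, `delta_qaly`.
#' @export
run_psa <- function(cfg, n = 10000L, seed = 20170101L, collapse = FALSE) {
  stopifnot(inherits(cfg, "study_config"), n >= 1)
  set.seed(seed)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    s <- if (collapse) collapse_to_means(cfg) else sample_parameters(cfg)
    run <- tryCatch(run_comparison(s, keep_trace = FALSE),
                    error = function(e) stop("PSA draw ", k, ": ",
                                             conditionMessage(e)))
    rows[[k]] <- data.frame(
      draw = k,
      p_opt_all_cause = s$probabilities$OPT$all_cause$base,
      p_icd_all_cause = s$probabilities$ICD$all_cause$base,
      u_well = s$utilities$well$base,
      device_price = s$costs$device_price$base,
      delta_cost = run$ce$delta_cost,
      delta_qaly = run$ce$delta_qaly)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' incremental net monetary benefit, `wtp * dQALY - dCost > 0`.
#'
#' @param samples A `psa_result` (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid Numeric vector of thresholds in USD/QALY; the default
#'   0 to 40,000 in steps of 500 covers both published thresholds (1x and 3x
#'   GDP per capita: 6,308 and 19,139).
#' @return Data frame with `wtp`, `probability_cost_effective`, and
#'   `mc_se` (the binomial Monte Carlo standard error of the probability).
#' @export
ceac <- function(samples, wtp_grid = c(seq(0, 40000, by = 500), 6308, 19139)) {
  stopifnot(nrow(samples) >= 1)
  wtp_grid <- sort(unique(wtp_grid))
  n <- nrow(samples)
  p <- vapply(wtp_grid, function(w)
    mean(w * samples$delta_qaly - samples$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = p,
             mc_se = sqrt(p * (1 - p) / n))
}

#' Probability of cost-effectiveness at one threshold
#'
#' @param samples A `psa_result`.
#' @param wtp Willingness to pay in USD/QALY.
#' @return List with `probability` and its binomial Monte Carlo `se`.
#' @export
prob_cost_effective <- function(samples, wtp) {
  p <- mean(wtp * samples$delta_qaly - samples$delta_cost > 0)
  list(probability = p, se = sqrt(p * (1 - p) / nrow(samples)))
}

#' Export PSA draws / CEAC as CSV
#'
#' @param samples A `psa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_psa <- function(samples, path) {
  utils::write.csv(samples[, c("draw", "delta_cost", "delta_qaly")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_psa
#' @param curve A data frame from [ceac()].
#' @export
export_ceac <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
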