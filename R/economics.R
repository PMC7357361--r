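# Decision quantities derived from a pair of arm results: incremental
# cost-effectiveness ratio, net monetary benefit, and the break-even device
# price at a willingness-to-pay threshold.

#' Incremental cost-effectiveness ratio
#'
#' Deltas are intervention minus comparator. When the signs of the deltas
#' differ one strategy dominates (cheaper and more effective) and the ICER is
#' not meaningful as a decision statistic; the dominance flag records which.
#'
#' @param intervention,comparator `arm_result` objects from [run_arm()], run
#'   under the same economic settings.
#' @return An object of class `ce_result`: `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when `delta_qaly` is 0), and `dominance` (one of `"none"`,
#'   `"intervention_dominates"`, `"comparator_dominates"`).
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  dc <- intervention$total_discounted_cost - comparator$total_discounted_cost
  de <- intervention$total_discounted_qaly - comparator$total_discounted_qaly
  dominance <- "none"
  if (de > 0 && dc < 0) dominance <- "intervention_dominates"
  if (de < 0 && dc > 0) dominance <- "comparator_dominates"
  structure(list(delta_cost = dc, delta_qaly = de,
                 icer = if (de == 0) NA_real_ else dc / de,
                 dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost USD %.2f, incremental QALY %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) {
    cat("ICER undefined (zero incremental QALY)\n")
  } else {
    cat(sprintf("ICER USD %.0f per QALY%s\n", x$icer,
                if (x$dominance != "none") paste0(" [", x$dominance, "]") else ""))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * QALY - cost` for one arm. The intervention has higher NMB than the
#' comparator exactly when its ICER is below the willingness to pay (for
#' positive incremental QALYs).
#'
#' @param result An `arm_result`.
#' @param wtp Willingness to pay in USD per QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(result, wtp) {
  stopifnot(inherits(result, "arm_result"), wtp >= 0)
  wtp * result$total_discounted_qaly - result$total_discounted_cost
}

#' Run both arms and compare
#'
#' Convenience wrapper: runs the ICD and OPT arms on one configuration and
#' returns the incremental comparison.
#'
#' @param cfg A `study_config`.
#' @param keep_trace Passed to [run_arm()].
#' @return A list with `OPT` and `ICD` `arm_result`s and `ce` (the
#'   [icer()] comparison, ICD vs OPT).
#' @export
run_comparison <- function(cfg, keep_trace = TRUE) {
  opt <- run_arm("OPT", cfg, keep_trace = keep_trace)
  icd <- run_arm("ICD", cfg, keep_trace = keep_trace)
  list(OPT = opt, ICD = icd, ce = icer(icd, opt))
}

#' Break-even device price at a willingness-to-pay threshold
#'
#' Searches the device price (applied wherever the device is paid for: at
#' implantation, in severe-infection management, and in replacements under
#' the active replacement policy) for which the ICER of ICD vs OPT equals
#' `wtp`. The ICER is monotone increasing in the device price, so the root is
#' unique; it is found with Brent's method on the bracket
#' `[0, bracket_factor * base price]` to within `tol` USD.
#'
#' @param cfg A `study_config`.
#' @param wtp Willingness to pay in USD per QALY.
#' @param tol Price tolerance in USD (default 1).
#' @param bracket_factor Upper bracket as a multiple of the base device price.
#' @return The break-even device price in USD.
#' @export
threshold_device_price <- function(cfg, wtp, tol = 1, bracket_factor = 5) {
  stopifnot(inherits(cfg, "study_config"), wtp > 0)
  base <- cfg$costs$device_price$base
  f <- function(price) {
    c2 <- cfg
    c2$costs$device_price <- cost_range(price, price, price)
    run <- run_comparison(c2, keep_trace = FALSE)
    run$ce$icer - wtp
  }
  lo <- 0; hi <- bracket_factor * base
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf("threshold_device_price: no sign change on [0, %.0f] for WTP %.0f",
                 hi, wtp))
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Export a cost-effectiveness table as CSV
#'
#' Two rows (comparator first) with the published table's columns: strategy,
#' cost, incremental cost, QALY, incremental QALY, ICER.
#'
#' @param comparison A list from [run_comparison()].
#' @param path Output CSV path.
#' @param digits Rounding for display columns (cost 2, QALY 4 by convention);
#'   `NA` keeps full precision.
#' @return The data frame written, invisibly.
#' @export
export_ce_table <- function(comparison, path, digits = TRUE) {
  ce <- comparison$ce
  tab <- data.frame(
    strategy = c("OPT", "OPT + ICD"),
    cost = c(comparison$OPT$total_discounted_cost,
             comparison$ICD$total_discounted_cost),
    incremental_cost = c(NA, ce$delta_cost),
    qaly = c(comparison$OPT$total_discounted_qaly,
             comparison$ICD$total_discounted_qaly),
    incremental_qaly = c(NA, ce$delta_qaly),
    icer = c(NA, ce$icer))
  if (isTRUE(digits)) {
    tab$cost <- round(tab$cost, 2); tab$incremental_cost <- round(tab$incremental_cost, 2)
    tab$qaly <- round(tab$qaly, 4); tab$incremental_qaly <- round(tab$incremental_qaly, 4)
    tab$icer <- round(tab$icer, 0)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}
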