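cfg0 <- fixture_config("base_case")

# base case with the background mortality switched off (q = 0), for checks
# whose arithmetic is stated without the life-table contribution
cfg_q0 <- cfg0
cfg_q0$life_table <- structure(
  data.frame(age = 60:79, q = 0), class = c("life_table", "data.frame"))
cfg_q0$life_table_spec <- NULL

test_that("implantation decision tree splits the cohort as specified", {
  e <- decision_tree_entry("OPT", cfg0)
  expect_equal(e$state[["well"]], 1)
  expect_equal(e$entry_cost, 0)
  e2 <- decision_tree_entry("ICD", cfg0)  # operative death is 0 in the base case
  expect_equal(e2$state[["well"]], 1)
  expect_equal(e2$entry_cost, 7259.46 + 300.28 + 73.39)
  cfg_op <- cfg0
  cfg_op$probabilities$ICD$operative_death$base <- 0.01
  e3 <- decision_tree_entry("ICD", cfg_op)
  expect_equal(e3$state[["well"]], 0.99)
  expect_equal(e3$state[["dead_operative"]], 0.01)
})

test_that("mortality decomposition is the subtraction rule with a floor at zero", {
  expect_equal(unname(decompose_mortality(0.284, 0.108, 0.012)),
               c(0.108, 0.164, 0.012))
  expect_equal(unname(decompose_mortality(0.178, 0.037, 0.012)),
               c(0.037, 0.129, 0.012))
  expect_warning(d <- decompose_mortality(0.10, 0.05, 0.20), "floored")
  expect_equal(unname(d), c(0.05, 0, 0.20))
  expect_error(decompose_mortality(0.05, 0.10, 0.01), "exceeds all-cause")
})

test_that("dead states are absorbing and the OPT arm loses exactly its all-cause mass", {
  dead <- stats::setNames(numeric(9), state_names())
  dead["dead_sudden_cardiac"] <- 1
  expect_equal(cycle_transition(dead, "ICD", cfg0, 60), dead)

  well <- stats::setNames(numeric(9), state_names()); well["well"] <- 1
  nxt <- cycle_transition(well, "OPT", cfg_q0, 60)
  expect_equal(sum(nxt[grep("^dead", names(nxt))]), 0.284)
  expect_equal(nxt[["well"]], 0.716)
})

test_that("ICD complications split survivors by the conditional shares", {
  well <- stats::setNames(numeric(9), state_names()); well["well"] <- 1
  nxt <- cycle_transition(well, "ICD", cfg_q0, 60)
  survivors <- 1 - 0.178
  entered <- survivors * 0.062
  comp_now <- sum(nxt[c("comp_movement", "comp_infection", "comp_fracture")])
  expect_equal(comp_now + nxt[["dead_infection"]], entered)     # 0.050964
  expect_equal(nxt[["comp_movement"]], entered * 0.5)
  expect_equal(nxt[["comp_fracture"]], entered * 0.3)
  expect_equal(nxt[["comp_infection"]], entered * 0.2 * (1 - 0.21))
  expect_equal(nxt[["dead_infection"]], entered * 0.2 * 0.21)
})

test_that("per-cycle accrual matches the stated base-case arithmetic", {
  well <- stats::setNames(numeric(9), state_names()); well["well"] <- 1
  a0 <- accrue_cycle(well, "OPT", cfg0, 0)
  expect_equal(a0[["cost"]], 313.04)
  expect_equal(a0[["qaly"]], 0.845)
  a2 <- accrue_cycle(well, "OPT", cfg0, 2)
  expect_equal(a2[["disc_qaly"]], 0.845 / 1.035^2)  # 0.78882
  expect_equal(a2[["disc_cost"]], 313.04 / 1.03^2)
  dead <- stats::setNames(numeric(9), state_names())
  dead["dead_noncardiac"] <- 1
  expect_equal(unname(accrue_cycle(dead, "ICD", cfg0, 3)), rep(0, 4))
  # replacement cycle charges all living ICD patients the device price
  a5 <- accrue_cycle(well, "ICD", cfg0, 5)
  expect_equal(a5[["cost"]], 313.04 + 7259.46)
  expect_equal(accrue_cycle(well, "OPT", cfg0, 5)[["cost"]], 313.04)
})

test_that("every trace conserves cohort mass to 1e-12 and dead mass never shrinks", {
  grids <- list(cfg0, fixture_config("twenty_year"),
                suppressWarnings(set_param(cfg0, "prob.ICD.complication", 0.3)),
                suppressWarnings(set_param(cfg0, "prob.OPT.all_cause", 0.6)),
                apply_relative_risks(cfg0))
  for (cfg in grids) for (arm in c("OPT", "ICD")) {
    tr <- run_arm(arm, cfg)$trace
    states <- tr[, state_names()]
    expect_true(all(abs(rowSums(states) - 1) < 1e-12))
    dead <- rowSums(states[, grep("^dead", state_names())])
    expect_true(all(diff(dead) >= -1e-15))
    expect_true(all(tr$disc_cost <= tr$cost + 1e-9))
    expect_true(all(tr$disc_qaly <= tr$qaly + 1e-9))
  }
})

test_that("engine agrees with brute-force path enumeration for short horizons", {
  for (h in 1:3) {
    cfg <- set_param(cfg0, "econ.horizon_years", h)
    # a replacement interval inside the horizon exercises the replacement
    # charge in the enumeration too
    if (h == 3) cfg <- set_param(cfg, "econ.replacement_interval_years", 2)
    for (arm in c("OPT", "ICD")) {
      res <- run_arm(arm, cfg)
      orc <- oracle_run_arm(arm, cfg)
      expect_equal(res$total_discounted_cost, orc[["cost"]], tolerance = 1e-10)
      expect_equal(res$total_discounted_qaly, orc[["qaly"]], tolerance = 1e-10)
    }
  }
  # and with a non-zero operative death probability
  cfg_op <- suppressWarnings(
    set_param(set_param(cfg0, "econ.horizon_years", 2),
              "prob.ICD.operative_death", 0.02))
  res <- run_arm("ICD", cfg_op)
  orc <- oracle_run_arm("ICD", cfg_op)
  expect_equal(res$total_discounted_cost, orc[["cost"]], tolerance = 1e-10)
  expect_equal(res$total_discounted_qaly, orc[["qaly"]], tolerance = 1e-10)
})

test_that("zero discount rates reproduce the undiscounted trace sums", {
  cfg <- cfg0
  cfg$econ$discount_rate_costs <- 0
  cfg$econ$discount_rate_qalys <- 0
  for (arm in c("OPT", "ICD")) {
    r <- run_arm(arm, cfg)
    expect_equal(r$total_discounted_cost, r$total_cost)
    expect_equal(r$total_discounted_qaly, r$total_qaly)
  }
})

test_that("totals equal the trace sums and discounting only shrinks them", {
  r <- run_arm("ICD", cfg0)
  expect_equal(r$total_discounted_cost, sum(r$trace$disc_cost), tolerance = 1e-9)
  expect_equal(r$total_discounted_qaly, sum(r$trace$disc_qaly), tolerance = 1e-9)
  expect_lt(r$total_discounted_qaly, r$total_qaly)
  expect_equal(nrow(r$trace), cfg0$econ$horizon_years)
})

test_that("QALYs rise with horizon and fall with each death probability", {
  q_at <- function(cfg, arm) run_arm(arm, cfg)$total_discounted_qaly
  horizons <- c(1, 2, 5, 10, 20)
  qs <- vapply(horizons, function(h)
    q_at(set_param(cfg0, "econ.horizon_years", h), "OPT"), numeric(1))
  expect_true(all(diff(qs) > 0))
  for (pm in c("prob.OPT.all_cause", "prob.ICD.all_cause")) {
    arm <- if (grepl("OPT", pm)) "OPT" else "ICD"
    base <- get <- NULL
    vals <- vapply(c(0.2, 0.3, 0.45, 0.6), function(v)
      q_at(suppressWarnings(set_param(cfg0, pm, v)), arm), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # higher death-from-infection probability also lowers ICD QALYs
  v <- vapply(c(0.05, 0.21, 0.6), function(x)
    q_at(suppressWarnings(set_param(cfg0, "prob.ICD.death_given_infection", x)),
         "ICD"), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("with base-case parameters the ICD arm costs more and yields more QALYs", {
  run <- run_comparison(cfg0)
  expect_gt(run$ICD$total_discounted_qaly, run$OPT$total_discounted_qaly)
  expect_gt(run$ICD$total_discounted_cost, run$OPT$total_discounted_cost)
})

test_that("trace export writes the fixed column order", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace(run_arm("OPT", cfg0), path)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("cycle", "age", state_names(), "cost", "qaly",
                     "disc_cost", "disc_qaly"))
  expect_equal(nrow(got), 10)
})
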