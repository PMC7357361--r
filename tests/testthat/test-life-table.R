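test_that("Gompertz table matches its closed form", {
  lt <- gompertz_life_table(0.02, 0.1, 60, 10)
  expect_equal(lt$q[1], 1 - exp(-0.02))        # 0.019801...
  expect_equal(lt$q[5], 1 - exp(-0.02 * exp(0.1 * 4)))
  expect_equal(lt$age, 60:69)
})

test_that("flat hazard gives a constant table, positive slope a strictly increasing one", {
  flat <- gompertz_life_table(0.01, 0, 60, 10)
  expect_true(all(abs(flat$q - (1 - exp(-0.01))) < 1e-15))
  inc <- gompertz_life_table(0.01, 0.09, 60, 10)
  expect_true(all(diff(inc$q) > 0))
})

test_that("extreme parameters saturate at probability 1 without overshooting", {
  lt <- gompertz_life_table(0.5, 0.5, 60, 15)
  expect_true(all(lt$q <= 1))
  expect_equal(lt$q[15], 1)  # hazard ~600/year: certain death
  expect_true(all(diff(lt$q) >= 0))
})

test_that("calibration hits the target first-year probability and doubling time", {
  lt <- calibrate_life_table(0.01, 8, 60, 10)
  expect_equal(lt$q[1], 0.01, tolerance = 1e-10)
  # hazard doubles every 8 years; q ratio tracks it closely at small q
  expect_equal(lt$q[9] / lt$q[1], 2, tolerance = 0.02)
  expect_error(calibrate_life_table(0.01, Inf, 60, 10), "finite")
  expect_error(calibrate_life_table(1.2, 8, 60, 10), "in \\(0, 1\\)")
})

test_that("generated tables satisfy the life-table invariants on a parameter grid", {
  grid <- expand.grid(q0 = c(0.001, 0.012, 0.05), dt = c(4, 8, 16),
                      n = c(1, 10, 40))
  for (i in seq_len(nrow(grid))) {
    lt <- calibrate_life_table(grid$q0[i], grid$dt[i], 60, grid$n[i])
    expect_equal(nrow(lt), grid$n[i])
    expect_true(all(lt$q >= 0 & lt$q <= 1))
    expect_true(all(diff(lt$q) >= 0))
    expect_identical(lt$age, 60:(60 + grid$n[i] - 1))
  }
})

test_that("default fixture table is the calibrated 1.2%/8-year schedule", {
  cfg <- fixture_config("base_case")
  expect_equal(cfg$life_table$q[1], 0.012, tolerance = 1e-10)
  expect_equal(cfg$life_table_spec$doubling_time_years, 8)
  expect_true(all(diff(cfg$life_table$q) >= 0))
})

test_that("life tables round-trip through CSV", {
  lt <- calibrate_life_table(0.012, 8, 60, 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(lt2$age, lt$age)
  expect_equal(lt2$q, lt$q, tolerance = 1e-12)
  expect_error(life_table_q(lt, 120), "not covered")
})

test_that("scenario fixtures override exactly one setting", {
  base <- fixture_config("base_case")
  five <- fixture_config("five_year")
  expect_equal(five$econ$horizon_years, 5L)
  expect_equal(five$probabilities, base$probabilities)
  expect_equal(five$costs, base$costs)
  r7 <- fixture_config("replacement_7y")
  expect_equal(r7$econ$replacement_interval_years, 7L)
  expect_equal(r7$econ$horizon_years, 10L)
  twenty <- fixture_config("twenty_year")
  expect_equal(twenty$econ$horizon_years, 20L)
  expect_equal(nrow(twenty$life_table), 20L)
})

test_that("subgroup stubs are flagged and refuse to run until completed", {
  stub <- fixture_config("ischemic_stub")
  expect_true(stub$meta$requires_user_input)
  expect_true(is.na(stub$probabilities$OPT$all_cause$base))
  expect_error(run_arm("OPT", stub), "placeholder")
  # substituting values makes the subgroup runnable
  stub$probabilities$OPT$all_cause$base <- 0.30
  stub$probabilities$OPT$sudden_cardiac$base <- 0.12
  stub$probabilities$ICD$all_cause$base <- 0.19
  stub$probabilities$ICD$sudden_cardiac$base <- 0.05
  stub$meta$requires_user_input <- FALSE
  expect_s3_class(run_arm("OPT", validate_config(stub)), "arm_result")
})
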