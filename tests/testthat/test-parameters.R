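test_that("beta_mean reproduces the published base-case probabilities", {
  cases <- list(
    list(a = 604, b = 1522, printed = 0.284),   # OPT all-cause mortality
    list(a = 317, b = 2605, printed = 0.108),   # OPT sudden cardiac death
    list(a = 110, b = 2825, printed = 0.037),   # ICD sudden cardiac death
    list(a = 169, b = 2554, printed = 0.062),   # ICD complications
    list(a = 16,  b = 16,   printed = 0.5),     # device movement
    list(a = 10,  b = 40,   printed = 0.2))     # infection
  for (cs in cases)
    expect_equal(round(beta_mean(beta_count(cs$a, cs$b)), 3), cs$printed)
  # the pooled ICD all-cause counts disagree with the printed 0.178 in the
  # third decimal (0.17701); the mismatch is below the 0.002 validation band
  expect_equal(beta_mean(beta_count(385, 1790)), 0.17701, tolerance = 1e-4)
  expect_equal(beta_mean(beta_count(1, 1)), 0.5)
  expect_equal(round(beta_mean(beta_count(6.164, 1.131)), 3), 0.845)
  expect_error(beta_count(0, 0), "alpha \\+ beta")
  expect_error(beta_count(-1, 2))
})

test_that("method-of-moments beta inversion matches the published death-from-infection row", {
  b <- beta_from_moments(0.2098, 0.1275)
  expect_equal(b$alpha, 1.93, tolerance = 0.02 / 1.93)
  expect_equal(b$beta, 7.27, tolerance = 0.02 / 7.27)
  expect_equal(round(beta_mean(b), 2), 0.21)
  expect_error(beta_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_from_moments(0, 0.1))
})

test_that("moment inversion round-trips any valid beta_count", {
  grid <- expand.grid(a = c(0.5, 1.93, 16, 604), b = c(1.131, 7.27, 40, 2825))
  for (i in seq_len(nrow(grid))) {
    b0 <- beta_count(grid$a[i], grid$b[i])
    b1 <- beta_from_moments(beta_mean(b0), beta_sd(b0))
    expect_equal(b1$alpha, b0$alpha, tolerance = 1e-9)
    expect_equal(b1$beta, b0$beta, tolerance = 1e-9)
  }
})

test_that("beta_interval brackets the mean and degenerates at alpha = 0", {
  b <- beta_count(169, 2554)
  ci <- beta_interval(b)
  expect_lt(ci[1], beta_mean(b)); expect_gt(ci[2], beta_mean(b))
  expect_equal(beta_interval(beta_count(0, 2774)), c(0, 0))
})

test_that("cost_range enforces min <= base <= max", {
  cr <- cost_range(7259.46, 6539.44, 7793.12)
  expect_s3_class(cr, "cost_range")
  expect_error(cost_range(100, 200, 50), "min <= base <= max")
  expect_error(cost_range(-1, -1, 0))
})

test_that("packaged base case carries the published values", {
  cfg <- fixture_config("base_case")
  expect_equal(cfg$costs$device_price$base, 7259.46)
  expect_equal(cfg$costs$opt_annual$base, 313.04)
  expect_equal(cfg$probabilities$OPT$all_cause$base, 0.284)
  expect_equal(cfg$probabilities$ICD$all_cause$base, 0.178)
  expect_equal(cfg$probabilities$ICD$operative_death$base, 0)
  expect_equal(cfg$utilities$well$base, 0.845)
  expect_equal(cfg$utilities$complication$base, 0.75)
  expect_equal(cfg$econ$horizon_years, 10L)
  expect_equal(cfg$econ$wtp_high, 19139)
  # residual fracture share of complications = 1 - movement - infection
  expect_equal(1 - cfg$probabilities$ICD$movement_given_complication$base -
                 cfg$probabilities$ICD$infection_given_complication$base, 0.3)
})

test_that("validation rejects broken configurations and warns on count mismatch", {
  cfg <- fixture_config("base_case")
  bad <- cfg; bad$probabilities$OPT$sudden_cardiac$base <- 0.5
  expect_error(suppressWarnings(validate_config(bad)), "exceeds all-cause")
  bad2 <- cfg; bad2$utilities$complication$base <- 0.9
  expect_error(validate_config(bad2), "complication utility")
  # base drifting > 0.002 from its beta mean flags a warning, not an error
  warned <- cfg; warned$probabilities$OPT$all_cause$base <- 0.30
  expect_warning(validate_config(warned), "differs from beta mean")
  # printed 0.178 vs count mean 0.17701 is inside the band: no warning
  expect_silent(validate_config(cfg))
})

test_that("configuration YAML round-trips through write_config/load_config", {
  cfg <- fixture_config("base_case")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  # writer is stable: write -> load -> write gives identical bytes
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("packaged YAML equals the in-code base case and overrides work", {
  cfg <- load_config(base_case_config_path())
  expect_equal(cfg, fixture_config("base_case"), tolerance = 1e-12)
  over <- set_param(cfg, "econ.horizon_years", 20)
  expect_equal(over$econ$horizon_years, 20L)
  over$econ$horizon_years <- cfg$econ$horizon_years
  over$life_table <- cfg$life_table
  expect_equal(over, cfg, tolerance = 1e-12)  # nothing else changed
})

test_that("config loader names missing fields and bad costs", {
  cfg <- fixture_config("base_case")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  l <- yaml::read_yaml(path)
  l$costs$device_price$base <- NULL
  path_bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(l, path_bad)
  expect_error(load_config(path_bad), "base")
  l2 <- yaml::read_yaml(path)
  l2$costs$device_price$min <- 9000  # min > base
  yaml::write_yaml(l2, path_bad)
  expect_error(load_config(path_bad), "min <= base <= max")
  expect_error(load_config("no/such/file.yaml"), "no such file")
})

test_that("relative-risk derivation rescales the ICD mortality probabilities", {
  cfg <- apply_relative_risks(fixture_config("base_case"))
  expect_equal(cfg$probabilities$ICD$all_cause$base, 0.73 * 0.284)
  expect_equal(cfg$probabilities$ICD$sudden_cardiac$base, 0.40 * 0.108)
  expect_equal(cfg$probabilities$OPT$all_cause$base, 0.284)
  expect_identical(cfg$meta$icd_probabilities, "rr_derived")
})
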