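test_that("generator honours arm sizes, follow-up, and event ordering", {
  p <- list(
    arm_parameters("sevelamer", 107, death_scale = 6.7, dialysis_scale = 4.4),
    arm_parameters("caco3", 105, death_scale = 3.9, dialysis_scale = 3.6)
  )
  d <- generate_trial(p, seed = 42)
  rec <- d$records
  counts <- table(rec$arm)
  expect_equal(unname(c(counts[["sevelamer"]], counts[["caco3"]])),
               c(107, 105))
  expect_true(all(rec$time_death_yrs > 0 & rec$time_death_yrs <= 3))
  expect_true(all(rec$time_dialysis_yrs > 0 & rec$time_dialysis_yrs <= 3))
  # no dialysis initiation after death
  expect_true(all(rec$time_dialysis_yrs <= rec$time_death_yrs))
  dead <- rec$event_death & rec$event_dialysis
  expect_true(all(rec$time_dialysis_yrs[dead] <= rec$time_death_yrs[dead]))
})

test_that("zero-hazard limit censors every death at the end of follow-up", {
  p <- list(arm_parameters("sevelamer", 200, death_scale = 1e9,
                           dialysis_scale = 1e9))
  d <- generate_trial(p, seed = 7)
  expect_true(all(!d$records$event_death))
  expect_true(all(d$records$time_death_yrs == 3))
  expect_true(all(!d$records$event_dialysis))
})

test_that("exponential event fraction matches the closed-form CDF", {
  # shape 1, scale s: P(event by 3y) = 1 - exp(-3/s)
  s <- 4
  n <- 10000
  p <- list(arm_parameters("sevelamer", n, death_scale = s,
                           dialysis_scale = 1e9))
  d <- generate_trial(p, seed = 11)
  expected <- 1 - exp(-3 / s)
  observed <- mean(d$records$event_death)
  tol <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), tol)
})

test_that("the same seed reproduces the dataset exactly", {
  p <- list(arm_parameters("caco3", 50, death_scale = 4,
                           dialysis_scale = 3))
  expect_identical(generate_trial(p, seed = 123),
                   generate_trial(p, seed = 123))
  expect_false(identical(generate_trial(p, seed = 123),
                         generate_trial(p, seed = 124)))
})

test_that("invalid arm parameters are rejected", {
  expect_error(arm_parameters("sevelamer", 10, death_scale = -1,
                              dialysis_scale = 2), "positive")
  expect_error(arm_parameters("sevelamer", 0, death_scale = 1,
                              dialysis_scale = 2), "positive")
  expect_error(arm_parameters("elsewhere", 10, death_scale = 1,
                              dialysis_scale = 2))
})

test_that("trial datasets round-trip through CSV", {
  p <- list(arm_parameters("sevelamer", 20, death_scale = 5,
                           dialysis_scale = 4))
  d <- generate_trial(p, seed = 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  d2 <- read_trial_csv(path, seed = d$seed)
  expect_equal(d2$records, d$records, tolerance = 1e-12)
  expect_error(read_trial_csv(withr::local_tempfile(fileext = ".csv",
                                                    lines = "a,b\n1,2")),
               "columns")
})

test_that("calibration reproduces the life-year and cost targets", {
  cfg <- default_config()
  cal <- calibrate_to_life_years(config = cfg)
  outs <- attr(cal, "outcomes")
  tgt <- cfg$calibration$targets
  for (arm in names(tgt)) {
    expect_lt(abs(outs[[arm]]$ly - tgt[[arm]]$ly), 0.05)
    expect_lt(abs(outs[[arm]]$cost_rm - tgt[[arm]]$cost_rm) /
                tgt[[arm]]$cost_rm, 0.05)
  }
  # idempotence: re-running the pipeline on the returned parameters
  # reproduces the same life-years
  for (arm in names(cal)) {
    p <- cal[[arm]]
    o <- outcome_from_hazards(
      hazard_spec("exponential", 1 / p$death_scale),
      hazard_spec("exponential", 1 / p$dialysis_scale),
      arm, cfg
    )
    expect_lt(abs(o$ly - tgt[[arm]]$ly), 0.05)
  }
})

test_that("calibration agrees with a coarse grid-search oracle", {
  cfg <- default_config()
  cfg$calibration$targets <- list(sevelamer = list(ly = 6.37))
  cal <- calibrate_to_life_years(
    target_ly_by_arm = list(sevelamer = 6.37), config = cfg,
    target_cost_by_arm = NULL
  )
  # grid over death scales; best grid point should bracket the root
  grid <- seq(5, 9, by = 0.1)
  errs <- vapply(grid, function(s) {
    outcome_from_hazards(hazard_spec("exponential", 1 / s),
                         hazard_spec("exponential",
                                     1 / cal$sevelamer$dialysis_scale),
                         "sevelamer", cfg)$ly - 6.37
  }, numeric(1))
  best <- grid[which.min(abs(errs))]
  expect_lt(abs(cal$sevelamer$death_scale - best), 0.1)
})

test_that("a fixed-point target returns the initial guess", {
  cfg <- default_config()
  # model output at the internal initial guess (scales 5, 5)
  o0 <- outcome_from_hazards(hazard_spec("exponential", 1 / 5),
                             hazard_spec("exponential", 1 / 5),
                             "sevelamer", cfg)
  cal <- calibrate_to_life_years(
    target_ly_by_arm = list(sevelamer = o0$ly), config = cfg,
    target_cost_by_arm = list(sevelamer = o0$cost_rm)
  )
  expect_equal(cal$sevelamer$death_scale, 5, tolerance = 1e-6)
  expect_equal(cal$sevelamer$dialysis_scale, 5, tolerance = 1e-6)
})

test_that("unreachable life-year targets raise a calibration error", {
  cfg <- default_config()
  expect_error(
    calibrate_to_life_years(target_ly_by_arm = list(sevelamer = 100),
                            config = cfg, target_cost_by_arm = NULL),
    "calibration error"
  )
})
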