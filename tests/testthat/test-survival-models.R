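test_that("Kaplan-Meier matches empirical survival without censoring", {
  d <- make_dataset(c(1, 2, 3, 3), c(TRUE, TRUE, TRUE, TRUE))
  km <- km_curve(d, "death", "sevelamer")
  expect_equal(km$survival[km$time == 1], 0.75)
  expect_equal(km$survival[km$time == 2], 0.5)
  expect_equal(km$survival[km$time == 3], 0)
})

test_that("Kaplan-Meier is identically one when everything is censored", {
  d <- make_dataset(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  km <- km_curve(d, "death", "sevelamer")
  expect_true(all(km$survival == 1))
})

test_that("Kaplan-Meier equals the hand-computed product limit", {
  # events at 1, 3, 5; censorings at 2, 4, 6:
  # S(1) = 5/6, S(3) = 5/6 * 3/4, S(5) = 5/6 * 3/4 * 1/2
  d <- make_dataset(1:6, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  km <- km_curve(d, "death", "sevelamer")
  expect_equal(km$survival[km$time == 1], 5 / 6)
  expect_equal(km$survival[km$time == 3], 5 / 6 * 3 / 4)
  expect_equal(km$survival[km$time == 5], 5 / 6 * 3 / 4 * 1 / 2)
})

test_that("empty arms and zero-event fits are rejected", {
  d <- make_dataset(c(1, 2), c(TRUE, TRUE), arm = "sevelamer")
  expect_error(km_curve(d, "death", "caco3"), "no records")
  d0 <- make_dataset(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_error(fit_parametric(d0, "death", "sevelamer", "exponential"),
               "degenerate")
  d1 <- make_dataset(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  expect_error(fit_parametric(d1, "death", "sevelamer", "weibull"),
               "degenerate")
})

test_that("the exponential MLE equals events over person-time", {
  p <- list(arm_parameters("sevelamer", 400, death_scale = 4,
                           dialysis_scale = 1e9))
  d <- generate_trial(p, seed = 5)
  fit <- fit_parametric(d, "death", "sevelamer", "exponential")
  closed_form <- sum(d$records$event_death) / sum(d$records$time_death_yrs)
  expect_equal(unname(fit$parameters[["rate"]]), closed_form,
               tolerance = 1e-5)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$log_likelihood)
})

test_that("exponential and weibull fits recover simulation truth", {
  # exponential data at rate 0.2/yr, n = 5000, censored at 3y
  n <- 5000
  p <- list(arm_parameters("sevelamer", n, death_scale = 5,
                           dialysis_scale = 1e9))
  d <- generate_trial(p, seed = 31)
  fe <- fit_parametric(d, "death", "sevelamer", "exponential")
  se_rate <- fe$parameters[["rate"]] / sqrt(fe$n_events)
  expect_lt(abs(fe$parameters[["rate"]] - 0.2), 3 * se_rate)
  # a weibull fit on the same data should find shape ~ 1
  fw <- fit_parametric(d, "death", "sevelamer", "weibull")
  expect_lt(abs(fw$parameters[["shape"]] - 1),
            3 * fw$parameters_se[["shape"]])
  # and the nested exponential should win on AIC
  expect_lt(fe$aic, fw$aic + 2)
  fa <- fit_parametric(d, "death", "sevelamer", "auto")
  expect_true(fa$aic <= min(fe$aic, fw$aic))
})

test_that("competing-risk conversion matches closed forms and an
           integration oracle", {
  # h_d = h_x = 0: identity rows
  s0 <- const_schedule(0, 0, 3)
  for (t in 1:3) expect_equal(s0$matrices[, , t], diag(3),
                              ignore_attr = TRUE)
  # h_d = ln 2, h_x = 0: one-cycle death probability exactly 1/2
  s1 <- const_schedule(log(2), 0, 1)
  expect_equal(s1$matrices[1, "dead", 1], 0.5)
  expect_equal(s1$matrices[2, "dead", 1], 0.5)
  # h_d = 0.1, h_x = 0.2: exit 1 - exp(-0.3), split 1:2
  s2 <- const_schedule(0.1, 0.2, 1)
  exit <- s2$matrices[1, "dialysis", 1] + s2$matrices[1, "dead", 1]
  expect_equal(exit, 1 - exp(-0.3), tolerance = 1e-12)
  expect_equal(s2$matrices[1, "dialysis", 1] / s2$matrices[1, "dead", 1],
               2, tolerance = 1e-12)
  # independent oracle: P(first event death in [0,1]) by numerical
  # integration of h_d * exp(-(h_d + h_x) t)
  oracle <- stats::integrate(function(t) 0.1 * exp(-0.3 * t), 0, 1,
                             rel.tol = 1e-12)$value
  expect_equal(s2$matrices[1, "dead", 1], oracle, tolerance = 1e-9)
})

test_that("schedules are row-stochastic with absorbing death and no
           return from dialysis", {
  specs <- list(
    const_schedule(0.15, 0.23, 60),
    build_transition_schedule(
      hazard_spec("weibull", c(shape = 1.4, scale = 8)),
      hazard_spec("weibull", c(shape = 0.7, scale = 5)), 60,
      arm_label = "caco3"
    ),
    build_transition_schedule(
      hazard_spec("gompertz", c(shape = 0.05, rate = 0.1)),
      hazard_spec("exponential", c(rate = 0.2)), 60,
      arm_label = "caco3"
    )
  )
  for (s in specs) {
    sums <- apply(s$matrices, c(1, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(s$matrices >= 0 & s$matrices <= 1))
    expect_true(all(s$matrices[3, 3, ] == 1))
    expect_true(all(s$matrices[2, 1, ] == 0))
  }
})

test_that("exponential schedules are constant and increasing weibull
           hazards give increasing exit probabilities", {
  se <- const_schedule(0.1, 0.2, 10)
  exit <- 1 - se$matrices[1, 1, ]
  expect_equal(diff(exit), rep(0, 9), tolerance = 1e-14)
  sw <- build_transition_schedule(
    hazard_spec("weibull", c(shape = 1.5, scale = 10)),
    hazard_spec("weibull", c(shape = 1.5, scale = 8)), 20,
    arm_label = "sevelamer"
  )
  expect_true(all(diff(1 - sw$matrices[1, 1, ]) > 0))
})

test_that("schedules export to long-format data frames", {
  s <- const_schedule(0.1, 0.2, 4, arm = "caco3")
  df <- as.data.frame(s)
  expect_equal(names(df),
               c("cycle", "from_state", "to_state", "probability", "arm"))
  expect_equal(nrow(df), 9 * 4)
  expect_true(all(df$arm == "caco3"))
  one <- df[df$cycle == 2 & df$from_state == "ckd_nd", ]
  expect_equal(sum(one$probability), 1, tolerance = 1e-12)
})
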