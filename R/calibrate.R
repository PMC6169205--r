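#' Lifetime outcome of one arm from its cause-specific hazards
#'
#' Convenience wrapper chaining [build_transition_schedule], [run_cohort]
#' and [value_trace] under a run configuration: the deterministic model
#' pipeline used for calibration, scenarios and the PSA.
#'
#' @param death,dialysis [hazard_spec]s (or `survival_fit`s) for the arm's
#'   death and dialysis-initiation hazards.
#' @param arm_label `"sevelamer"` or `"caco3"`.
#' @param config a `run_config` (see [default_config]).
#' @return a `strategy_outcome`.
#' @export
outcome_from_hazards <- function(death, dialysis, arm_label,
                                 config = default_config()) {
  sched <- build_transition_schedule(death, dialysis,
                                     config$model$horizon_years,
                                     arm_label = arm_label)
  trace <- run_cohort(sched)
  value_trace(trace,
              costs = config_cost_inputs(config),
              utilities = config_utility_inputs(config),
              discount = config_discount_spec(config),
              half_cycle_correction = config$model$half_cycle_correction)
}

weibull_spec <- function(shape, scale) {
  if (shape == 1) {
    hazard_spec("exponential", c(rate = 1 / scale))
  } else {
    hazard_spec("weibull", c(shape = shape, scale = scale))
  }
}

#' Calibrate arm hazards to published lifetime outcomes
#'
#' Finds, for each arm, Weibull scale parameters (at fixed shape, default 1
#' i.e. exponential) for the death and dialysis-initiation hazards such
#' that the full lifetime model reproduces the target discounted life-years
#' — and, when per-arm lifetime-cost targets are given (the default config
#' carries both), the target discounted lifetime cost. Discounted
#' life-years respond mainly to the death scale and lifetime cost mainly to
#' the dialysis scale, but in the discrete-cycle competing-risk
#' formulation life-years also depend weakly on the dialysis hazard, so
#' the two one-dimensional root-finds ([stats::uniroot] on the log-scale)
#' are alternated to joint convergence.
#'
#' @param target_ly_by_arm named list/vector of target discounted
#'   life-years per arm (default: the config's calibration targets).
#' @param config a `run_config`; supplies all valuation inputs, the
#'   horizon, the fixed shape and (unless overridden) the cost targets.
#' @param target_cost_by_arm optional named list/vector of target
#'   discounted lifetime costs (RM) per arm; `NULL` leaves the dialysis
#'   scale at its initial value and calibrates life-years only.
#' @param tolerance maximum absolute life-year error accepted (default
#'   0.05; also applied, relatively scaled, to cost targets).
#' @param max_iter maximum alternating sweeps.
#' @return named list (by arm) of [arm_parameters] whose Weibull
#'   parameters encode the calibrated hazards; the achieved outcomes and
#'   iteration trace are attached as attributes `"outcomes"` and
#'   `"trace"`.
#' @export
calibrate_to_life_years <- function(target_ly_by_arm = NULL,
                                    config = default_config(),
                                    target_cost_by_arm = NULL,
                                    tolerance = NULL,
                                    max_iter = 60) {
  tgt <- config$calibration$targets
  if (is.null(target_ly_by_arm)) {
    target_ly_by_arm <- lapply(tgt, `[[`, "ly")
  }
  if (is.null(target_cost_by_arm) && !is.null(tgt) &&
      all(vapply(tgt, function(x) !is.null(x$cost_rm), logical(1)))) {
    target_cost_by_arm <- lapply(tgt, `[[`, "cost_rm")
  }
  tolerance <- tolerance %||% config$calibration$tolerance_ly %||% 0.05
  shape <- config$calibration$shape %||% 1
  arms <- names(target_ly_by_arm)
  stopifnot(length(arms) >= 1, all(arms %in% .arms))
  horizon <- config$model$horizon_years
  # maximum attainable discounted LY: zero hazard, full annuity
  ly_max <- sum(discount_factor(config$discount$outcomes, 0:(horizon - 1)))

  n_by_arm <- c(sevelamer = config$trial$n_sevelamer,
                caco3 = config$trial$n_caco3)
  out <- list()
  traces <- list()
  for (arm in arms) {
    t_ly <- as.numeric(target_ly_by_arm[[arm]])
    t_cost <- if (!is.null(target_cost_by_arm)) {
      as.numeric(target_cost_by_arm[[arm]])
    }
    if (t_ly <= 0 || t_ly >= ly_max) {
      stop("calibration error: target ", signif(t_ly, 4),
           " discounted life-years for '", arm,
           "' is outside the attainable range (0, ", signif(ly_max, 4),
           ") for a ", horizon, "-year horizon", call. = FALSE)
    }
    eval_model <- function(scale_d, scale_x) {
      outcome_from_hazards(weibull_spec(shape, scale_d),
                           weibull_spec(shape, scale_x),
                           arm_label = arm, config = config)
    }
    scale_d <- 5
    scale_x <- 5
    trace <- data.frame()
    o <- NULL
    for (it in seq_len(max_iter)) {
      scale_d_new <- tryCatch(
        exp(uniroot(
          function(ls) eval_model(exp(ls), scale_x)$ly - t_ly,
          lower = log(0.02), upper = log(5e4), tol = 1e-12
        )$root),
        error = function(e) {
          stop("calibration error: life-year target ", signif(t_ly, 4),
               " for '", arm, "' is not bracketed by the scale search ",
               "interval (", conditionMessage(e), ")", call. = FALSE)
        }
      )
      scale_x_new <- if (is.null(t_cost)) {
        scale_x
      } else {
        # cost decreases as the dialysis scale grows (less dialysis time)
        f <- function(ls) eval_model(scale_d_new, exp(ls))$cost_rm - t_cost
        lo <- log(0.02); hi <- log(1e7)
        if (f(lo) < 0 || f(hi) > 0) {
          stop("calibration error: lifetime-cost target ",
               signif(t_cost, 6), " for '", arm,
               "' is unattainable at the calibrated death hazard",
               call. = FALSE)
        }
        exp(uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root)
      }
      o <- eval_model(scale_d_new, scale_x_new)
      trace <- rbind(trace, data.frame(
        iter = it, scale_death = scale_d_new, scale_dialysis = scale_x_new,
        ly = o$ly, cost_rm = o$cost_rm
      ))
      step <- max(abs(scale_d_new - scale_d) / scale_d_new,
                  abs(scale_x_new - scale_x) / scale_x_new)
      scale_d <- scale_d_new
      scale_x <- scale_x_new
      if (step < 1e-10) break
    }
    within <- abs(o$ly - t_ly) <= tolerance &&
      (is.null(t_cost) || abs(o$cost_rm - t_cost) <= tolerance * abs(t_cost))
    if (!within) {
      stop("calibration error: no convergence for arm '", arm, "' after ",
           it, " sweeps; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"),
           call. = FALSE)
    }
    out[[arm]] <- arm_parameters(
      arm_label = arm,
      n_patients = n_by_arm[[arm]] %||% 100L,
      death_shape = shape, death_scale = scale_d,
      dialysis_shape = shape, dialysis_scale = scale_x,
      followup_months = config$trial$followup_months %||% 36
    )
    traces[[arm]] <- trace
  }
  attr(out, "outcomes") <- lapply(out, function(p) {
    outcome_from_hazards(weibull_spec(p$death_shape, p$death_scale),
                         weibull_spec(p$dialysis_shape, p$dialysis_scale),
                         arm_label = p$arm_label, config = config)
  })
  attr(out, "trace") <- traces
  out
}

# hazard specs of a calibrated arm
arm_hazards <- function(p) {
  list(death = weibull_spec(p$death_shape, p$death_scale),
       dialysis = weibull_spec(p$dialysis_shape, p$dialysis_scale))
}
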