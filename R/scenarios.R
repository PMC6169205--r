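#' Built-in deterministic scenario set
#'
#' The ten one-way scenarios of the published sensitivity analysis:
#' undiscounted and 5%-discounted results, 3- and 10-year horizons, high
#' sevelamer (4.8 g/day) and high calcium carbonate (7.5 g/day) doses, low
#' dialysis utility (0.72), low/high haemodialysis cost (RM 197.48 /
#' RM 350), and exclusion of dialysis cost.
#'
#' @return list of `scenario_spec`s (`id`, `label`, `overrides` with
#'   dotted config-key paths).
#' @export
builtin_scenarios <- function() {
  sc <- function(id, label, overrides) {
    structure(list(id = id, label = label, overrides = overrides),
              class = "scenario_spec")
  }
  list(
    sc("1a", "Undiscounted cost and outcomes",
       list("discount.costs" = 0, "discount.outcomes" = 0)),
    sc("1b", "5% discount rate",
       list("discount.costs" = 0.05, "discount.outcomes" = 0.05)),
    sc("2a", "3-year time horizon", list("model.horizon_years" = 3L)),
    sc("2b", "10-year time horizon", list("model.horizon_years" = 10L)),
    sc("3a", "High sevelamer dose (4.8 g/day)",
       list("drugs.sevelamer.dose_g_per_day" = 4.8)),
    sc("3b", "High CaCO3 dose (7.5 g/day)",
       list("drugs.caco3.dose_g_per_day" = 7.5)),
    sc("4", "Low dialysis utility (0.72)",
       list("utilities.dialysis" = 0.72)),
    sc("5a", "Low HD cost (RM197.48/session)",
       list("dialysis.hd_cost_rm_per_session" = 197.48)),
    sc("5b", "High HD cost (RM350/session)",
       list("dialysis.hd_cost_rm_per_session" = 350)),
    sc("6", "Exclude dialysis cost",
       list("dialysis.hd_cost_rm_per_session" = 0,
            "dialysis.capd_cost_rm_per_day" = 0))
  )
}

# Apply dotted-path overrides to a config, rejecting unknown keys.
apply_overrides <- function(config, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- config
    for (i in seq_along(parts)) {
      if (!is.list(node) || !parts[i] %in% names(node)) {
        stop("unknown config key in scenario override: '", key, "'",
             call. = FALSE)
      }
      node <- node[[parts[i]]]
    }
    config[[parts]] <- overrides[[key]]
  }
  validate_config(config)
  config
}

#' Run one deterministic scenario
#'
#' Applies the scenario's parameter overrides to the base configuration and
#' re-runs the full valuation with the arm hazards held at their base-case
#' calibration (scenarios probe the economics, not the calibrated
#' epidemiology; overriding a discount rate does not re-target the
#' published discounted life-years).
#'
#' @param base_config a `run_config`.
#' @param scenario a `scenario_spec` (see [builtin_scenarios]), or a plain
#'   named list of overrides.
#' @param calibrated calibrated parameters from [calibrate_to_life_years];
#'   computed from `base_config` when omitted.
#' @return a `ce_result`; the scenario's per-arm `strategy_outcome`s are
#'   attached as attribute `"outcomes"`.
#' @export
run_scenario <- function(base_config, scenario, calibrated = NULL) {
  overrides <- if (inherits(scenario, "scenario_spec")) {
    scenario$overrides
  } else {
    scenario
  }
  if (is.null(calibrated)) {
    calibrated <- calibrate_to_life_years(config = base_config)
  }
  cfg <- apply_overrides(base_config, overrides)
  outs <- lapply(calibrated, function(p) {
    h <- arm_hazards(p)
    outcome_from_hazards(h$death, h$dialysis, p$arm_label, cfg)
  })
  res <- icer(outs$sevelamer, outs$caco3)
  attr(res, "outcomes") <- outs
  res
}
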