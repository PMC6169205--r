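#' Cost inputs (2013 Ringgit Malaysia)
#'
#' Unit costs and resource-use assumptions. Defaults are the published base
#' case: average daily doses from the source trial, Malaysian public-sector
#' drug prices, haemodialysis (HD) costed at 3 sessions/week (156 per
#' year), continuous ambulatory peritoneal dialysis (CAPD) daily (365 days
#' per year), and a registry-based 88%/12% HD/CAPD modality mix.
#'
#' @param drug_dose_g_per_day named vector of daily doses (g) per arm.
#' @param drug_price_rm_per_g named vector of unit prices (RM/g) per arm.
#' @param hd_cost_rm_per_session,hd_sessions_per_year HD unit cost and
#'   annual frequency.
#' @param capd_cost_rm_per_day,capd_days_per_year CAPD unit cost and annual
#'   frequency.
#' @param hd_share,capd_share dialysis modality mix; must sum to 1.
#' @param binder_continues_on_dialysis if `TRUE` (default) the phosphate
#'   binder is still prescribed after dialysis inception, so dialysis-state
#'   cycles accrue drug cost on top of dialysis cost.
#' @return an object of class `cost_inputs`.
#' @export
cost_inputs <- function(drug_dose_g_per_day = c(sevelamer = 2.184,
                                                caco3 = 2.950),
                        drug_price_rm_per_g = c(sevelamer = 5.0069,
                                                caco3 = 0.0871),
                        hd_cost_rm_per_session = 259.09,
                        hd_sessions_per_year = 156,
                        capd_cost_rm_per_day = 99.04,
                        capd_days_per_year = 365,
                        hd_share = 0.88,
                        capd_share = 0.12,
                        binder_continues_on_dialysis = TRUE) {
  vals <- c(drug_dose_g_per_day, drug_price_rm_per_g,
            hd_cost_rm_per_session, hd_sessions_per_year,
            capd_cost_rm_per_day, capd_days_per_year, hd_share, capd_share)
  if (anyNA(vals) || any(vals < 0)) {
    stop("cost inputs must be non-negative", call. = FALSE)
  }
  if (abs(hd_share + capd_share - 1) > 1e-9) {
    stop("hd_share + capd_share must equal 1", call. = FALSE)
  }
  structure(list(
    drug_dose_g_per_day = drug_dose_g_per_day,
    drug_price_rm_per_g = drug_price_rm_per_g,
    hd_cost_rm_per_session = hd_cost_rm_per_session,
    hd_sessions_per_year = hd_sessions_per_year,
    capd_cost_rm_per_day = capd_cost_rm_per_day,
    capd_days_per_year = capd_days_per_year,
    hd_share = hd_share, capd_share = capd_share,
    binder_continues_on_dialysis = isTRUE(binder_continues_on_dialysis)
  ), class = "cost_inputs")
}

#' Health-state utilities
#'
#' @param predialysis utility while alive without dialysis (default 0.86).
#' @param dialysis utility on dialysis (default 0.80).
#' @return an object of class `utility_inputs`; death carries utility 0.
#' @export
utility_inputs <- function(predialysis = 0.86, dialysis = 0.8) {
  if (anyNA(c(predialysis, dialysis)) ||
      any(c(predialysis, dialysis) < 0) ||
      any(c(predialysis, dialysis) > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(predialysis = predialysis, dialysis = dialysis, dead = 0),
            class = "utility_inputs")
}

#' Annual discount rates
#'
#' @param rate_costs,rate_outcomes annual rates (default 0.03 each,
#'   per Malaysian pharmacoeconomic guidance).
#' @return an object of class `discount_spec`.
#' @export
discount_spec <- function(rate_costs = 0.03, rate_outcomes = 0.03) {
  if (anyNA(c(rate_costs, rate_outcomes)) || rate_costs < 0 ||
      rate_outcomes < 0) {
    stop("discount rates must be non-negative", call. = FALSE)
  }
  structure(list(rate_costs = rate_costs, rate_outcomes = rate_outcomes),
            class = "discount_spec")
}

#' Annual drug cost
#'
#' Daily dose times unit price times 365 days.
#'
#' @param dose_g_per_day daily dose (g).
#' @param price_rm_per_g unit price (RM/g).
#' @return RM per patient-year.
#' @examples
#' annual_drug_cost(2.184, 5.0069) # sevelamer, ~RM 3991.30/yr
#' @export
annual_drug_cost <- function(dose_g_per_day, price_rm_per_g) {
  if (anyNA(c(dose_g_per_day, price_rm_per_g)) || dose_g_per_day < 0 ||
      price_rm_per_g < 0) {
    stop("dose and price must be non-negative", call. = FALSE)
  }
  dose_g_per_day * price_rm_per_g * 365
}

#' Annual dialysis cost averaged over modality mix
#'
#' `hd_share * (sessions * hd_cost) + capd_share * (days * capd_cost)`.
#'
#' @param costs a [cost_inputs].
#' @return RM per dialysis patient-year.
#' @export
annual_dialysis_cost <- function(costs) {
  stopifnot(inherits(costs, "cost_inputs"))
  costs$hd_share * costs$hd_sessions_per_year * costs$hd_cost_rm_per_session +
    costs$capd_share * costs$capd_days_per_year * costs$capd_cost_rm_per_day
}

#' Discount factor for a model cycle
#'
#' @param rate annual rate (>= 0).
#' @param cycle_index cycle number, 0 for the reference year.
#' @return `(1 + rate)^(-cycle_index)`.
#' @export
discount_factor <- function(rate, cycle_index) {
  stopifnot(all(rate >= 0), all(cycle_index >= 0))
  (1 + rate)^(-cycle_index)
}

#' Value a cohort trace: discounted lifetime cost, life-years and QALYs
#'
#' Attaches the economics to a cohort trace. Cycle `t` accrues, per
#' patient, `occ_ckd(t) * drug + occ_dial(t) * (dialysis + drug * binder)`
#' in cost, `occ_ckd(t) + occ_dial(t)` in life-years, and utility-weighted
#' occupancy in QALYs, where `occ` is state occupancy at the start of the
#' cycle (full-year accrual) and `binder` is 1 when the phosphate binder
#' continues on dialysis. The dead state accrues nothing. Totals are
#' discounted at `(1 + r)^-t` with cycle 0 undiscounted; undiscounted
#' counterparts are always reported alongside. With
#' `half_cycle_correction = TRUE` the accrual basis for cycle `t` is the
#' mean of the start- and end-of-cycle occupancies instead.
#'
#' @param trace a `cohort_trace` (its `arm_label` selects the drug dose and
#'   price from `costs`).
#' @param costs a [cost_inputs].
#' @param utilities a [utility_inputs].
#' @param discount a [discount_spec].
#' @param half_cycle_correction average start/end occupancy per cycle
#'   (default `FALSE`).
#' @param keep_cycles attach the per-cycle valuation table as attribute
#'   `"cycles"`.
#' @return a `strategy_outcome`: `arm_label`, discounted `cost_rm`, `ly`,
#'   `qaly`, and undiscounted counterparts (`*_undisc`).
#' @export
value_trace <- function(trace, costs = cost_inputs(),
                        utilities = utility_inputs(),
                        discount = discount_spec(),
                        half_cycle_correction = FALSE,
                        keep_cycles = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_inputs"),
            inherits(utilities, "utility_inputs"),
            inherits(discount, "discount_spec"))
  arm <- trace$arm_label
  if (is.null(arm) || !arm %in% names(costs$drug_dose_g_per_day) ||
      !arm %in% names(costs$drug_price_rm_per_g)) {
    stop("trace arm label '", arm %||% "NULL",
         "' has no dose/price in cost inputs", call. = FALSE)
  }
  drug <- annual_drug_cost(costs$drug_dose_g_per_day[[arm]],
                           costs$drug_price_rm_per_g[[arm]])
  dial <- annual_dialysis_cost(costs)
  n <- trace$cycles
  occ <- trace$occupancy
  basis <- if (half_cycle_correction) {
    (occ[1:n, , drop = FALSE] + occ[2:(n + 1), , drop = FALSE]) / 2
  } else {
    occ[1:n, , drop = FALSE]
  }
  cost_cycle <- basis[, 1] * drug +
    basis[, 2] * (dial + drug * costs$binder_continues_on_dialysis)
  ly_cycle <- basis[, 1] + basis[, 2]
  qaly_cycle <- utilities$predialysis * basis[, 1] +
    utilities$dialysis * basis[, 2]
  vc <- discount_factor(discount$rate_costs, 0:(n - 1))
  vo <- discount_factor(discount$rate_outcomes, 0:(n - 1))
  out <- structure(list(
    arm_label = arm,
    cost_rm = sum(cost_cycle * vc),
    ly = sum(ly_cycle * vo),
    qaly = sum(qaly_cycle * vo),
    cost_rm_undisc = sum(cost_cycle),
    ly_undisc = sum(ly_cycle),
    qaly_undisc = sum(qaly_cycle)
  ), class = "strategy_outcome")
  if (keep_cycles) {
    attr(out, "cycles") <- data.frame(
      cycle = 0:(n - 1), cost_rm = cost_cycle, ly = ly_cycle,
      qaly = qaly_cycle, discount_costs = vc, discount_outcomes = vo,
      arm = arm
    )
  }
  out
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat("<strategy_outcome> ", x$arm_label, "\n", sep = "")
  cat(sprintf("  discounted:   RM %s, %.2f LY, %.2f QALY\n",
              format(round(x$cost_rm), big.mark = ","), x$ly, x$qaly))
  cat(sprintf("  undiscounted: RM %s, %.2f LY, %.2f QALY\n",
              format(round(x$cost_rm_undisc), big.mark = ","),
              x$ly_undisc, x$qaly_undisc))
  invisible(x)
}
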