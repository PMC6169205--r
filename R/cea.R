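#' WHO-style willingness-to-pay thresholds
#'
#' @param gdp_per_capita_rm projected GDP per capita of the reference year
#'   (default RM 33,132, Malaysia 2013).
#' @param multiples threshold multiples of GDP (default 1, 2, 3).
#' @param usd_exchange_rate RM per USD (default 3.28, 31 Dec 2013).
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(gdp_per_capita_rm = 33132, multiples = c(1, 2, 3),
                          usd_exchange_rate = 3.28) {
  if (gdp_per_capita_rm <= 0 || usd_exchange_rate <= 0 ||
      any(multiples <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(gdp_per_capita_rm = gdp_per_capita_rm,
                 multiples = multiples,
                 usd_exchange_rate = usd_exchange_rate),
            class = "threshold_set")
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Deltas are intervention minus comparator; the ICER is the ratio of the
#' incremental cost to the incremental effect. When the intervention is
#' cheaper and more effective it dominates (no ICER is reported); costlier
#' and less effective, it is dominated. A zero effect delta leaves the
#' corresponding ICER undefined (`NA`) with `icer_defined = FALSE` rather
#' than failing.
#'
#' @param outcome_intervention,outcome_comparator `strategy_outcome`s.
#' @return a `ce_result` with `delta_cost_rm`, `delta_ly`, `delta_qaly`,
#'   `icer_per_ly`, `icer_per_qaly`, `dominance_flag` (`"none"`,
#'   `"intervention_dominant"`, `"intervention_dominated"`) and
#'   `icer_defined`.
#' @examples
#' a <- structure(list(arm_label = "sevelamer", cost_rm = 100, ly = 10,
#'                     qaly = 10), class = "strategy_outcome")
#' b <- structure(list(arm_label = "caco3", cost_rm = 50, ly = 5,
#'                     qaly = 5), class = "strategy_outcome")
#' icer(a, b)$icer_per_qaly # 10
#' @export
icer <- function(outcome_intervention, outcome_comparator) {
  stopifnot(inherits(outcome_intervention, "strategy_outcome"),
            inherits(outcome_comparator, "strategy_outcome"))
  dc <- outcome_intervention$cost_rm - outcome_comparator$cost_rm
  dl <- outcome_intervention$ly - outcome_comparator$ly
  dq <- outcome_intervention$qaly - outcome_comparator$qaly
  dominance <- if (dc < 0 && dq > 0) {
    "intervention_dominant"
  } else if (dc > 0 && dq < 0) {
    "intervention_dominated"
  } else {
    "none"
  }
  defined <- dominance == "none" && dq != 0
  structure(list(
    intervention = outcome_intervention$arm_label,
    comparator = outcome_comparator$arm_label,
    delta_cost_rm = dc, delta_ly = dl, delta_qaly = dq,
    icer_per_ly = if (dominance == "none" && dl != 0) dc / dl else NA_real_,
    icer_per_qaly = if (defined) dc / dq else NA_real_,
    dominance_flag = dominance,
    icer_defined = defined
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", x$intervention, " vs ", x$comparator, "\n", sep = "")
  cat(sprintf("  dCost RM %s, dLY %.3f, dQALY %.3f\n",
              format(round(x$delta_cost_rm), big.mark = ","),
              x$delta_ly, x$delta_qaly))
  if (x$dominance_flag != "none") {
    cat("  ", x$dominance_flag, "\n", sep = "")
  } else if (x$icer_defined) {
    cat(sprintf("  ICER RM %s/LY, RM %s/QALY\n",
                format(round(x$icer_per_ly), big.mark = ","),
                format(round(x$icer_per_qaly), big.mark = ",")))
  } else {
    cat("  ICER undefined (zero effect delta)\n")
  }
  invisible(x)
}

#' WHO cost-effectiveness category of an ICER
#'
#' At or below one GDP per capita per QALY: highly cost-effective; between
#' one and three: cost-effective; above three: not cost-effective. Boundary
#' ties go to the more favourable category.
#'
#' @param icer_per_qaly finite ICER (RM per QALY).
#' @param thresholds a [threshold_set].
#' @return `"highly_cost_effective"`, `"cost_effective"` or
#'   `"not_cost_effective"`.
#' @export
who_category <- function(icer_per_qaly, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"),
            is.finite(icer_per_qaly))
  gdp <- thresholds$gdp_per_capita_rm
  if (icer_per_qaly <= gdp) {
    "highly_cost_effective"
  } else if (icer_per_qaly <= 3 * gdp) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert Ringgit Malaysia to US dollars
#'
#' Divides by the exchange rate and rounds half away from zero to whole
#' dollars (the convention used for the published conversions, e.g.
#' RM 159,901 at 3.28 RM/USD is $48,750).
#'
#' @param amount_rm amount in RM.
#' @param exchange_rate RM per USD (> 0).
#' @return integer USD amount(s).
#' @export
rm_to_usd <- function(amount_rm, exchange_rate = 3.28) {
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  round_half_up(amount_rm / exchange_rate)
}
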