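#' Parameter distributions for the probabilistic sensitivity analysis
#'
#' Distribution assumptions for the PSA, all centred so the arithmetic
#' mean equals the base-case value:
#'
#' * treatment-effect hazard ratios (death, dialysis initiation; sevelamer
#'   vs comparator) — lognormal with `meanlog = log(base) - sdlog^2 / 2`;
#' * daily doses and drug unit prices — gamma, parameterised by a
#'   coefficient of variation;
#' * state utilities — beta, parameterised by a standard error via the
#'   method of moments.
#'
#' A dispersion of zero degenerates that parameter to its base value.
#'
#' @param cv_doses,cv_costs coefficients of variation for doses and drug
#'   unit prices (default 0.1 each).
#' @param se_log_hr standard error of the log hazard ratios (default 0.15).
#' @param se_utility standard error of the utilities (default 0.05).
#' @return an object of class `psa_distributions`.
#' @export
psa_distributions <- function(cv_doses = 0.1, cv_costs = 0.1,
                              se_log_hr = 0.15, se_utility = 0.05) {
  vals <- c(cv_doses, cv_costs, se_log_hr, se_utility)
  if (anyNA(vals) || any(vals < 0)) {
    stop("dispersions must be non-negative", call. = FALSE)
  }
  structure(list(cv_doses = cv_doses, cv_costs = cv_costs,
                 se_log_hr = se_log_hr, se_utility = se_utility),
            class = "psa_distributions")
}

config_psa_distributions <- function(cfg) {
  psa_distributions(cv_doses = cfg$psa$cv_doses, cv_costs = cfg$psa$cv_costs,
                    se_log_hr = cfg$psa$se_log_hr,
                    se_utility = cfg$psa$se_utility)
}

# mean-preserving samplers; dispersion 0 gives a point mass at the mean
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

rlnorm_mean <- function(n, mean, sdlog) {
  if (sdlog == 0) return(rep(mean, n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rbeta_mean_se <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop("utility SE ", se, " too large for mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of the uncertain inputs — treatment-effect hazard
#' ratios, daily doses, drug unit prices and state utilities — with the
#' full model re-run per draw. Treatment-effect uncertainty is made
#' explicit by holding the comparator arm's calibrated cause-specific
#' hazards fixed and inducing the sevelamer arm as a proportional scaling
#' of them by the drawn hazard ratios (the base-case ratios being those
#' implied by calibration).
#'
#' @param base_config a `run_config`.
#' @param distributions a [psa_distributions] (default: from the config).
#' @param n_sims number of draws (default: from the config, 10,000).
#' @param seed integer seed (default: from the config).
#' @param calibrated calibrated parameters from [calibrate_to_life_years];
#'   computed from `base_config` when omitted.
#' @return a `psa_result`: `draws` (data.frame with `delta_cost_rm`,
#'   `delta_ly`, `delta_qaly`), `n_sims`, `seed`, the base-case `ce_result`
#'   as `base`, and the sampled parameter matrix as attribute `"samples"`.
#' @export
run_psa <- function(base_config, distributions = NULL, n_sims = NULL,
                    seed = NULL, calibrated = NULL) {
  cfg <- base_config
  distributions <- distributions %||% config_psa_distributions(cfg)
  n_sims <- n_sims %||% cfg$psa$n_sims
  seed <- seed %||% cfg$seed
  stopifnot(n_sims >= 1)
  if (is.null(calibrated)) {
    calibrated <- calibrate_to_life_years(config = cfg)
  }
  hz_s <- arm_hazards(calibrated$sevelamer)
  hz_c <- arm_hazards(calibrated$caco3)
  # base-case hazard ratios implied by the calibration
  hr_death <- cum_hazard(hz_s$death, 1) / cum_hazard(hz_c$death, 1)
  hr_dial <- cum_hazard(hz_s$dialysis, 1) / cum_hazard(hz_c$dialysis, 1)

  d <- distributions
  samples <- with_seed(seed, data.frame(
    hr_death = rlnorm_mean(n_sims, hr_death, d$se_log_hr),
    hr_dialysis = rlnorm_mean(n_sims, hr_dial, d$se_log_hr),
    dose_sevelamer = rgamma_mean_cv(n_sims,
                                    cfg$drugs$sevelamer$dose_g_per_day,
                                    d$cv_doses),
    dose_caco3 = rgamma_mean_cv(n_sims, cfg$drugs$caco3$dose_g_per_day,
                                d$cv_doses),
    price_sevelamer = rgamma_mean_cv(n_sims,
                                     cfg$drugs$sevelamer$price_rm_per_g,
                                     d$cv_costs),
    price_caco3 = rgamma_mean_cv(n_sims, cfg$drugs$caco3$price_rm_per_g,
                                 d$cv_costs),
    u_predialysis = rbeta_mean_se(n_sims, cfg$utilities$predialysis,
                                  d$se_utility),
    u_dialysis = rbeta_mean_se(n_sims, cfg$utilities$dialysis, d$se_utility)
  ))

  horizon <- cfg$model$horizon_years
  disc <- config_discount_spec(cfg)
  hcc <- cfg$model$half_cycle_correction
  # comparator trace never changes across draws
  trace_c <- run_cohort(build_transition_schedule(hz_c$death, hz_c$dialysis,
                                                  horizon,
                                                  arm_label = "caco3"))
  draws <- matrix(NA_real_, n_sims, 3,
                  dimnames = list(NULL,
                                  c("delta_cost_rm", "delta_ly",
                                    "delta_qaly")))
  for (i in seq_len(n_sims)) {
    s <- samples[i, ]
    cost_i <- cost_inputs(
      drug_dose_g_per_day = c(sevelamer = s$dose_sevelamer,
                              caco3 = s$dose_caco3),
      drug_price_rm_per_g = c(sevelamer = s$price_sevelamer,
                              caco3 = s$price_caco3),
      hd_cost_rm_per_session = cfg$dialysis$hd_cost_rm_per_session,
      hd_sessions_per_year = cfg$dialysis$hd_sessions_per_year,
      capd_cost_rm_per_day = cfg$dialysis$capd_cost_rm_per_day,
      capd_days_per_year = cfg$dialysis$capd_days_per_year,
      hd_share = cfg$dialysis$hd_share,
      capd_share = cfg$dialysis$capd_share,
      binder_continues_on_dialysis = cfg$drugs$binder_continues_on_dialysis
    )
    util_i <- utility_inputs(s$u_predialysis, s$u_dialysis)
    sched_s <- build_transition_schedule(
      scale_hazard(hz_c$death, s$hr_death),
      scale_hazard(hz_c$dialysis, s$hr_dialysis),
      horizon, arm_label = "sevelamer"
    )
    out_s <- value_trace(run_cohort(sched_s), cost_i, util_i, disc,
                         half_cycle_correction = hcc)
    out_c <- value_trace(trace_c, cost_i, util_i, disc,
                         half_cycle_correction = hcc)
    draws[i, ] <- c(out_s$cost_rm - out_c$cost_rm, out_s$ly - out_c$ly,
                    out_s$qaly - out_c$qaly)
  }
  base_outcomes <- attr(calibrated, "outcomes")
  structure(list(
    draws = as.data.frame(draws),
    n_sims = n_sims, seed = seed,
    base = icer(base_outcomes$sevelamer, base_outcomes$caco3),
    distributions = distributions
  ), class = "psa_result", samples = samples)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_sims, " draws, seed ", x$seed, "\n", sep = "")
  print(summary(x$draws))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay `lambda`, the fraction of PSA draws with
#' non-negative incremental net monetary benefit,
#' `lambda * delta_qaly - delta_cost >= 0`. Draws that are cost-saving and
#' effective satisfy this at every `lambda` (they are cost-effective at any
#' willingness-to-pay).
#'
#' @param psa_result a `psa_result`.
#' @param wtp_grid non-negative willingness-to-pay values (RM/QALY);
#'   default 0 to 4 x GDP per capita in steps of GDP/20.
#' @param thresholds a [threshold_set] (used only for the default grid).
#' @return data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa_result, wtp_grid = NULL, thresholds = threshold_set()) {
  stopifnot(inherits(psa_result, "psa_result"))
  d <- psa_result$draws
  if (nrow(d) == 0) stop("empty PSA draws", call. = FALSE)
  if (is.null(wtp_grid)) {
    gdp <- thresholds$gdp_per_capita_rm
    wtp_grid <- seq(0, 4 * gdp, by = gdp / 20)
  }
  stopifnot(all(wtp_grid >= 0))
  prob <- vapply(wtp_grid, function(l) {
    mean(l * d$delta_qaly - d$delta_cost_rm >= 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Fraction of PSA draws cost-effective at a threshold
#'
#' A draw counts as below the threshold when its incremental net monetary
#' benefit at that willingness-to-pay is non-negative: effective draws
#' (`delta_qaly > 0`) with `delta_cost / delta_qaly <= threshold`,
#' including dominant (cost-saving, effective) draws; draws that cost more
#' and gain nothing (`delta_qaly <= 0`, `delta_cost > 0`) count as above.
#'
#' @param psa_result a `psa_result`.
#' @param threshold_rm_per_qaly willingness-to-pay threshold (> 0).
#' @return proportion in `[0, 1]`.
#' @export
fraction_below_threshold <- function(psa_result, threshold_rm_per_qaly) {
  stopifnot(inherits(psa_result, "psa_result"),
            threshold_rm_per_qaly > 0)
  d <- psa_result$draws
  mean(threshold_rm_per_qaly * d$delta_qaly - d$delta_cost_rm >= 0)
}

#' Cost-effectiveness plane scatter of PSA draws
#'
#' @param psa_result a `psa_result`.
#' @param thresholds a [threshold_set]; its 1x/2x/3x GDP lines are drawn
#'   through the origin.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa_result, thresholds = threshold_set()) {
  stopifnot(inherits(psa_result, "psa_result"))
  d <- psa_result$draws
  gdp <- thresholds$gdp_per_capita_rm
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly,
                                  y = .data$delta_cost_rm)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0,
                         slope = thresholds$multiples * gdp,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "Incremental QALYs",
                  y = "Incremental cost (RM)",
                  title = "Cost-effectiveness plane",
                  subtitle = paste0(psa_result$n_sims,
                                    " PSA draws; dashed: GDP multiples")) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df output of [ceac].
#' @param thresholds a [threshold_set]; GDP multiples are marked.
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_df, thresholds = threshold_set()) {
  gdp <- thresholds$gdp_per_capita_rm
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp,
                                        y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = thresholds$multiples * gdp,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (RM per QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
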