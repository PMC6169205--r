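#' Default run configuration (published base case)
#'
#' Returns the full configuration tree with every input at its base-case
#' value: trial doses and Malaysian unit costs, utilities, dialysis
#' modality mix, 3% discounting, 60-year horizon, calibration targets
#' (discounted life-years and lifetime cost per arm), trial arm sizes and
#' 36-month follow-up, WHO thresholds, and PSA settings (10,000 draws with
#' the default dispersions). The same tree, serialised, ships as
#' `inst/extdata/base_case.yaml`.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    drugs = list(
      sevelamer = list(dose_g_per_day = 2.184, price_rm_per_g = 5.0069),
      caco3 = list(dose_g_per_day = 2.950, price_rm_per_g = 0.0871),
      binder_continues_on_dialysis = TRUE
    ),
    dialysis = list(
      hd_cost_rm_per_session = 259.09,
      hd_sessions_per_year = 156,
      capd_cost_rm_per_day = 99.04,
      capd_days_per_year = 365,
      hd_share = 0.88,
      capd_share = 0.12
    ),
    utilities = list(predialysis = 0.86, dialysis = 0.8),
    discount = list(costs = 0.03, outcomes = 0.03),
    model = list(
      horizon_years = 60L,
      cohort_size = 1000L,
      half_cycle_correction = FALSE,
      background_mortality = FALSE
    ),
    calibration = list(
      shape = 1,
      tolerance_ly = 0.05,
      targets = list(
        sevelamer = list(ly = 6.37, cost_rm = 159901),
        caco3 = list(ly = 4.25, cost_rm = 77139)
      )
    ),
    trial = list(
      n_sevelamer = 107L,
      n_caco3 = 105L,
      followup_months = 36
    ),
    thresholds = list(gdp_per_capita_rm = 33132, usd_exchange_rate = 3.28),
    psa = list(
      n_sims = 10000L,
      cv_doses = 0.1,
      cv_costs = 0.1,
      se_log_hr = 0.15,
      se_utility = 0.05
    ),
    seed = 20130919L
  ), class = "run_config")
}

#' Load and validate a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; any key not
#' present in the default tree is rejected, so typos fail loudly with the
#' full field path. Basic range checks (shares summing to one, positive
#' horizon, utilities in `[0, 1]`) are applied after merging.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return a validated `run_config`; the source file's MD5 (or `"default"`)
#'   is attached as attribute `"config_hash"`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "")
    attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  } else {
    attr(cfg, "config_hash") <- "default"
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) {
    stop("config entry '", sub("^\\.", "", prefix),
         "' must be a mapping", call. = FALSE)
  }
  for (k in names(user)) {
    path <- paste0(prefix, ".", k)
    if (!k %in% names(base)) {
      stop("unknown config key: '", sub("^\\.", "", path), "'",
           call. = FALSE)
    }
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], path)
    } else {
      v <- user[[k]]
      if (!is.atomic(v) || length(v) != 1 || is.na(v)) {
        stop("config key '", sub("^\\.", "", path),
             "' must be a single non-missing value", call. = FALSE)
      }
      base[[k]] <- v
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    if (abs(dialysis$hd_share + dialysis$capd_share - 1) > 1e-9) {
      stop("dialysis shares must sum to 1", call. = FALSE)
    }
    if (model$horizon_years < 1) stop("horizon must be >= 1", call. = FALSE)
    if (utilities$predialysis < 0 || utilities$predialysis > 1 ||
        utilities$dialysis < 0 || utilities$dialysis > 1) {
      stop("utilities must lie in [0, 1]", call. = FALSE)
    }
    if (discount$costs < 0 || discount$outcomes < 0) {
      stop("discount rates must be non-negative", call. = FALSE)
    }
    if (calibration$shape <= 0) stop("shape must be positive", call. = FALSE)
  })
  invisible(cfg)
}

# Adapters from the config tree to the valuation input objects.
config_cost_inputs <- function(cfg) {
  cost_inputs(
    drug_dose_g_per_day = c(sevelamer = cfg$drugs$sevelamer$dose_g_per_day,
                            caco3 = cfg$drugs$caco3$dose_g_per_day),
    drug_price_rm_per_g = c(sevelamer = cfg$drugs$sevelamer$price_rm_per_g,
                            caco3 = cfg$drugs$caco3$price_rm_per_g),
    hd_cost_rm_per_session = cfg$dialysis$hd_cost_rm_per_session,
    hd_sessions_per_year = cfg$dialysis$hd_sessions_per_year,
    capd_cost_rm_per_day = cfg$dialysis$capd_cost_rm_per_day,
    capd_days_per_year = cfg$dialysis$capd_days_per_year,
    hd_share = cfg$dialysis$hd_share,
    capd_share = cfg$dialysis$capd_share,
    binder_continues_on_dialysis = cfg$drugs$binder_continues_on_dialysis
  )
}

config_utility_inputs <- function(cfg) {
  utility_inputs(cfg$utilities$predialysis, cfg$utilities$dialysis)
}

config_discount_spec <- function(cfg) {
  discount_spec(cfg$discount$costs, cfg$discount$outcomes)
}

config_thresholds <- function(cfg) {
  threshold_set(gdp_per_capita_rm = cfg$thresholds$gdp_per_capita_rm,
                usd_exchange_rate = cfg$thresholds$usd_exchange_rate)
}
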