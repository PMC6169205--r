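#' Run the base-case analysis
#'
#' Calibrates the arm hazards to the configured lifetime targets, runs the
#' Markov model for both strategies and assembles the base-case report:
#' per-arm discounted cost, life-years and QALYs, the incremental row,
#' ICERs per life-year and per QALY, the WHO threshold category and
#' USD conversions.
#'
#' @param config a `run_config` (see [load_run_config]).
#' @return a `base_case_report` list with elements `strategies`,
#'   `incremental`, `who_category`, `usd`, `table` (a Table-3-shaped
#'   data.frame), `calibrated`, and `meta`.
#' @examples
#' \donttest{
#' rep <- run_base_case(default_config())
#' rep$table
#' }
#' @export
run_base_case <- function(config = default_config()) {
  calibrated <- calibrate_to_life_years(config = config)
  outs <- attr(calibrated, "outcomes")
  inc <- icer(outs$sevelamer, outs$caco3)
  thr <- config_thresholds(config)
  fx <- thr$usd_exchange_rate
  category <- if (inc$icer_defined) {
    who_category(inc$icer_per_qaly, thr)
  } else {
    NA_character_
  }
  tab <- data.frame(
    treatment = c("caco3", "sevelamer", "incremental"),
    cost_rm = c(outs$caco3$cost_rm, outs$sevelamer$cost_rm,
                inc$delta_cost_rm),
    ly = c(outs$caco3$ly, outs$sevelamer$ly, inc$delta_ly),
    icer_per_ly = c(NA, NA, inc$icer_per_ly),
    qaly = c(outs$caco3$qaly, outs$sevelamer$qaly, inc$delta_qaly),
    icer_per_qaly = c(NA, NA, inc$icer_per_qaly)
  )
  structure(list(
    strategies = outs,
    incremental = inc,
    who_category = category,
    usd = list(
      cost_sevelamer = rm_to_usd(outs$sevelamer$cost_rm, fx),
      cost_caco3 = rm_to_usd(outs$caco3$cost_rm, fx),
      icer_per_ly = if (is.na(inc$icer_per_ly)) NA_real_ else
        rm_to_usd(inc$icer_per_ly, fx),
      icer_per_qaly = if (is.na(inc$icer_per_qaly)) NA_real_ else
        rm_to_usd(inc$icer_per_qaly, fx)
    ),
    table = tab,
    calibrated = calibrated,
    meta = run_meta(config)
  ), class = "base_case_report")
}

#' @export
print.base_case_report <- function(x, ...) {
  cat("== Base case (discounted) ==\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  cat("WHO category:", x$who_category, "\n")
  cat(sprintf("USD: cost %s vs %s; ICER $%s/QALY\n",
              format(x$usd$cost_sevelamer, big.mark = ","),
              format(x$usd$cost_caco3, big.mark = ","),
              format(x$usd$icer_per_qaly, big.mark = ",")))
  invisible(x)
}

#' Run the deterministic scenario set
#'
#' @param config a `run_config`.
#' @param scenarios list of `scenario_spec`s (default [builtin_scenarios]).
#' @return a `scenario_report`: data.frame `table` with one row per
#'   scenario (id, label, ICER per QALY, change vs base, WHO category) plus
#'   the per-scenario `ce_result`s in `results` and `meta`.
#' @export
run_scenarios <- function(config = default_config(),
                          scenarios = builtin_scenarios()) {
  calibrated <- calibrate_to_life_years(config = config)
  base_outs <- attr(calibrated, "outcomes")
  base <- icer(base_outs$sevelamer, base_outs$caco3)
  thr <- config_thresholds(config)
  results <- lapply(scenarios, function(s) {
    run_scenario(config, s, calibrated = calibrated)
  })
  names(results) <- vapply(scenarios, `[[`, character(1), "id")
  tab <- data.frame(
    id = names(results),
    label = vapply(scenarios, `[[`, character(1), "label"),
    icer_per_qaly = vapply(results, `[[`, numeric(1), "icer_per_qaly"),
    pct_change_vs_base = vapply(results, function(r) {
      100 * (r$icer_per_qaly / base$icer_per_qaly - 1)
    }, numeric(1)),
    who_category = vapply(results, function(r) {
      if (r$icer_defined) who_category(r$icer_per_qaly, thr)
      else NA_character_
    }, character(1))
  )
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, base = base,
                 meta = run_meta(config)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("== Scenario sensitivity analysis ==\n")
  cat(sprintf("base ICER: RM %s/QALY\n",
              format(round(x$base$icer_per_qaly), big.mark = ",")))
  tab <- x$table
  tab$icer_per_qaly <- round(tab$icer_per_qaly)
  tab$pct_change_vs_base <- round(tab$pct_change_vs_base, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the PSA and summarise it against GDP thresholds
#'
#' @param config a `run_config`.
#' @param n_sims,seed optional overrides of the config's PSA settings.
#' @return a `psa_report`: the `psa_result`, the [ceac] curve, and
#'   `fraction_below` at 1x/2x/3x GDP per capita.
#' @export
run_psa_report <- function(config = default_config(), n_sims = NULL,
                           seed = NULL) {
  psa <- run_psa(config, n_sims = n_sims, seed = seed)
  thr <- config_thresholds(config)
  gdp <- thr$gdp_per_capita_rm
  curve <- ceac(psa, thresholds = thr)
  frac <- vapply(thr$multiples, function(m) {
    fraction_below_threshold(psa, m * gdp)
  }, numeric(1))
  names(frac) <- paste0(thr$multiples, "x_gdp")
  structure(list(psa = psa, ceac = curve, fraction_below = frac,
                 meta = run_meta(config)),
            class = "psa_report")
}

#' @export
print.psa_report <- function(x, ...) {
  cat("== Probabilistic sensitivity analysis ==\n")
  cat(x$psa$n_sims, "draws, seed", x$psa$seed, "\n")
  cat("fraction of draws cost-effective at GDP multiples:\n")
  print(round(100 * x$fraction_below, 1))
  invisible(x)
}

run_meta <- function(config) {
  list(
    package = "binderCEA",
    version = as.character(packageVersion("binderCEA")),
    seed = config$seed,
    config_hash = attr(config, "config_hash") %||% "default"
  )
}

#' Write a report to JSON (and its tables to CSV)
#'
#' Serialises a base-case, scenario or PSA report deterministically (no
#' timestamps; identical inputs give byte-identical files). The JSON
#' carries the run metadata (package version, seed, config hash); tabular
#' components (trace/draw/curve tables) are written as CSV next to the
#' JSON file.
#'
#' @param report a `base_case_report`, `scenario_report` or `psa_report`.
#' @param path output JSON path; CSVs share its stem.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stem <- sub("\\.json$", "", path)
  paths <- path
  if (inherits(report, "base_case_report")) {
    body <- list(
      meta = report$meta,
      table = report$table,
      who_category = report$who_category,
      usd = report$usd
    )
    write.csv(report$table, paste0(stem, "_table.csv"), row.names = FALSE)
    paths <- c(paths, paste0(stem, "_table.csv"))
  } else if (inherits(report, "scenario_report")) {
    body <- list(meta = report$meta, table = report$table)
    write.csv(report$table, paste0(stem, "_table.csv"), row.names = FALSE)
    paths <- c(paths, paste0(stem, "_table.csv"))
  } else if (inherits(report, "psa_report")) {
    body <- list(
      meta = report$meta,
      n_sims = report$psa$n_sims,
      seed = report$psa$seed,
      fraction_below = as.list(report$fraction_below)
    )
    write.csv(report$psa$draws, paste0(stem, "_draws.csv"),
              row.names = FALSE)
    write.csv(report$ceac, paste0(stem, "_ceac.csv"), row.names = FALSE)
    paths <- c(paths, paste0(stem, "_draws.csv"), paste0(stem, "_ceac.csv"))
  } else {
    stop("unknown report type", call. = FALSE)
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(paths)
}
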