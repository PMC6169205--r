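#' Kaplan-Meier estimate for one endpoint and arm
#'
#' Product-limit estimator of the survivor function of either trial
#' endpoint (overall survival, or dialysis-free "survival" treating death
#' as censoring for the cause-specific dialysis endpoint), computed with
#' [survival::survfit].
#'
#' @param dataset a `trial_dataset`.
#' @param endpoint `"death"` or `"dialysis"`.
#' @param arm `"sevelamer"` or `"caco3"`.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`;
#'   a step function with `S(0) = 1` implicit and steps only at event
#'   times.
#' @export
km_curve <- function(dataset, endpoint = c("death", "dialysis"),
                     arm = c("sevelamer", "caco3")) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  d <- endpoint_data(dataset, endpoint, arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

endpoint_data <- function(dataset, endpoint, arm) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rec <- dataset$records[dataset$records$arm == arm, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records in arm '", arm, "'", call. = FALSE)
  if (endpoint == "death") {
    data.frame(time = rec$time_death_yrs, event = rec$event_death)
  } else {
    data.frame(time = rec$time_dialysis_yrs, event = rec$event_dialysis)
  }
}

#' Parametric survival fit for one endpoint and arm
#'
#' Right-censored maximum-likelihood fit of an exponential, Weibull or
#' Gompertz model (via [flexsurv::flexsurvreg]), used to extrapolate the
#' 36-month trial endpoints over the lifetime horizon. `family = "auto"`
#' fits all three and keeps the lowest AIC.
#'
#' @inheritParams km_curve
#' @param family `"exponential"`, `"weibull"`, `"gompertz"` or `"auto"`.
#' @return a `survival_fit`: endpoint, arm, family, fitted parameters,
#'   log-likelihood, AIC, and the corresponding [hazard_spec].
#' @export
fit_parametric <- function(dataset, endpoint = c("death", "dialysis"),
                           arm = c("sevelamer", "caco3"),
                           family = c("exponential", "weibull", "gompertz",
                                      "auto")) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  family <- match.arg(family)
  d <- endpoint_data(dataset, endpoint, arm)
  if (family == "auto") {
    fits <- lapply(c("exponential", "weibull", "gompertz"), function(f) {
      tryCatch(fit_parametric(dataset, endpoint, arm, f),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) stop("no family could be fitted", call. = FALSE)
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]])
  }
  nev <- sum(d$event)
  kpar <- if (family == "exponential") 1L else 2L
  if (nev < kpar) {
    stop("degenerate fit: ", nev, " event(s) cannot identify a ", kpar,
         "-parameter ", family, " model", call. = FALSE)
  }
  dist <- c(exponential = "exp", weibull = "weibull",
            gompertz = "gompertz")[[family]]
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                              dist = dist)
  est <- setNames(fs$res[, "est"], rownames(fs$res))
  se <- setNames(fs$res[, "se"], rownames(fs$res))
  params <- switch(family,
    exponential = c(rate = unname(est["rate"])),
    weibull = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    gompertz = c(shape = unname(est["shape"]), rate = unname(est["rate"]))
  )
  spec <- if (family == "gompertz" && params[["shape"]] == 0) {
    hazard_spec("exponential", c(rate = params[["rate"]]))
  } else {
    hazard_spec(family, params)
  }
  structure(list(
    endpoint = endpoint, arm_label = arm, family = family,
    parameters = params, parameters_se = se,
    log_likelihood = as.numeric(stats::logLik(fs)),
    aic = stats::AIC(fs),
    n = nrow(d), n_events = nev,
    hazard = spec
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit> ", x$endpoint, " / ", x$arm_label, " / ", x$family,
      "  (n=", x$n, ", events=", x$n_events, ")\n", sep = "")
  print(signif(x$parameters, 6))
  cat("logLik ", signif(x$log_likelihood, 6), ", AIC ", signif(x$aic, 6),
      "\n", sep = "")
  invisible(x)
}

as_hazard <- function(x) {
  if (inherits(x, "hazard_spec")) return(x)
  if (inherits(x, "survival_fit")) return(x$hazard)
  stop("expected a hazard_spec or survival_fit", call. = FALSE)
}

#' Per-cycle transition matrices from cause-specific hazards
#'
#' Converts the fitted death and dialysis-initiation hazards of one arm
#' into annual transition matrices over the states (CKD not on dialysis,
#' dialysis, dead). For cycle `t` the cause-specific cumulative-hazard
#' increments over `[t, t+1)` are `h_d` (death) and `h_x` (dialysis); from
#' the predialysis state the standard competing-risk conversion gives
#' \deqn{P(dead) = \frac{h_d}{h_d+h_x}\,(1 - e^{-(h_d+h_x)}), \quad
#'       P(dialysis) = \frac{h_x}{h_d+h_x}\,(1 - e^{-(h_d+h_x)}),}
#' with the remainder staying put; from the dialysis state only death
#' competes, \eqn{P(dead) = 1 - e^{-h_d}} (the death hazard is applied
#' identically from both alive states); dead is absorbing. A cycle with
#' `h_d + h_x = 0` yields an identity row.
#'
#' @param fit_death,fit_dialysis `survival_fit` or [hazard_spec] for one
#'   arm's death and dialysis endpoints.
#' @param horizon_years number of one-year cycles (>= 1).
#' @param arm_label arm the schedule belongs to (taken from `fit_death`
#'   when it is a `survival_fit`).
#' @return a `transition_schedule`: `arm_label`, `cycles`, and `matrices`,
#'   a `3 x 3 x cycles` array; every row sums to one to 1e-12.
#' @examples
#' h_d <- hazard_spec("exponential", log(2)) # one-year death prob. 0.5
#' h_x <- hazard_spec("exponential", 1e-12)
#' s <- build_transition_schedule(h_d, h_x, 5, arm_label = "caco3")
#' s$matrices[, , 1]
#' @export
build_transition_schedule <- function(fit_death, fit_dialysis, horizon_years,
                                      arm_label = NULL) {
  if (is.null(arm_label) && inherits(fit_death, "survival_fit")) {
    arm_label <- fit_death$arm_label
  }
  stopifnot(horizon_years >= 1, horizon_years == round(horizon_years))
  hd_spec <- as_hazard(fit_death)
  hx_spec <- as_hazard(fit_dialysis)
  tt <- 0:horizon_years
  h_d <- diff(cum_hazard(hd_spec, tt))
  h_x <- diff(cum_hazard(hx_spec, tt))
  if (any(h_d < 0) || any(h_x < 0)) {
    stop("negative hazard increment in schedule", call. = FALSE)
  }
  mats <- array(0, dim = c(3, 3, horizon_years),
                dimnames = list(.states, .states, NULL))
  tot <- h_d + h_x
  p_exit <- -expm1(-tot)
  frac_d <- ifelse(tot > 0, h_d / tot, 0)
  p_dead_ckd <- frac_d * p_exit
  p_dial_ckd <- p_exit - p_dead_ckd
  p_dead_dial <- -expm1(-h_d)
  for (t in seq_len(horizon_years)) {
    mats[1, , t] <- c(1 - p_exit[t], p_dial_ckd[t], p_dead_ckd[t])
    mats[2, , t] <- c(0, 1 - p_dead_dial[t], p_dead_dial[t])
    mats[3, , t] <- c(0, 0, 1)
  }
  structure(list(arm_label = arm_label, cycles = horizon_years,
                 matrices = mats,
                 hazards = list(death = hd_spec, dialysis = hx_spec)),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule> arm ", x$arm_label %||% "?", ", ",
      x$cycles, " annual cycles\n", sep = "")
  cat("cycle 1 matrix:\n")
  print(round(x$matrices[, , 1], 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format export of a transition schedule
#'
#' @param x a `transition_schedule`.
#' @param ... unused.
#' @return data.frame with columns `cycle`, `from_state`, `to_state`,
#'   `probability`, `arm`.
#' @export
as.data.frame.transition_schedule <- function(x, ...) {
  g <- expand.grid(from_state = .states, to_state = .states,
                   cycle = seq_len(x$cycles), stringsAsFactors = FALSE)
  g$probability <- as.vector(x$matrices)
  g$arm <- x$arm_label %||% NA_character_
  g[, c("cycle", "from_state", "to_state", "probability", "arm")]
}
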