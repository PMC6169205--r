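#' Arm-level parameters for the synthetic trial generator
#'
#' Describes one treatment arm of the emulated two-arm phosphate-binder
#' trial: Weibull parameters (time scale years) for the latent time to
#' death and time to dialysis initiation, the number of randomised
#' patients, and the administrative follow-up. Shape 1 gives exponential
#' (constant-hazard) event times, the default used for calibration.
#'
#' @param arm_label `"sevelamer"` or `"caco3"`.
#' @param n_patients number of patients in the arm.
#' @param death_shape,death_scale Weibull shape/scale of latent death time.
#' @param dialysis_shape,dialysis_scale Weibull shape/scale of latent
#'   dialysis-initiation time.
#' @param followup_months administrative censoring time (default 36).
#' @return an object of class `arm_parameters`.
#' @export
arm_parameters <- function(arm_label, n_patients,
                           death_shape = 1, death_scale,
                           dialysis_shape = 1, dialysis_scale,
                           followup_months = 36) {
  arm_label <- match.arg(arm_label, .arms)
  vals <- c(n_patients = n_patients,
            death_shape = death_shape, death_scale = death_scale,
            dialysis_shape = dialysis_shape, dialysis_scale = dialysis_scale,
            followup_months = followup_months)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("all arm parameters must be strictly positive", call. = FALSE)
  }
  if (n_patients < 1 || n_patients != round(n_patients)) {
    stop("'n_patients' must be a positive integer", call. = FALSE)
  }
  structure(as.list(c(list(arm_label = arm_label), as.list(vals))),
            class = "arm_parameters")
}

# Evaluate the RNG-dependent expression with a locally seeded, restored RNG
# stream so callers' .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate synthetic individual-patient trial data
#'
#' Draws, for every patient, independent latent Weibull times to death and
#' to dialysis initiation, then applies the trial observation scheme:
#' administrative censoring at the end of follow-up, and censoring of the
#' dialysis endpoint at death (dialysis cannot be initiated after death, so
#' the dialysis time is the cause-specific, death-censored time). Within the
#' generator dialysis initiation does not modify the latent death time;
#' post-dialysis dynamics are carried by the Markov model, not the
#' generator.
#'
#' @param params_by_arm list of [arm_parameters], one per arm.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a `trial_dataset`: list with `records` (data.frame with columns
#'   `patient_id`, `arm`, `time_death_yrs`, `event_death`,
#'   `time_dialysis_yrs`, `event_dialysis`) and `seed`.
#' @examples
#' p <- list(
#'   arm_parameters("sevelamer", 107, death_scale = 6.7, dialysis_scale = 4.4),
#'   arm_parameters("caco3", 105, death_scale = 3.9, dialysis_scale = 3.6)
#' )
#' d <- generate_trial(p, seed = 20130919)
#' table(d$records$arm)
#' @export
generate_trial <- function(params_by_arm, seed = 20130919) {
  stopifnot(length(params_by_arm) >= 1)
  lapply(params_by_arm, function(p) {
    if (!inherits(p, "arm_parameters")) {
      stop("'params_by_arm' must contain arm_parameters objects",
           call. = FALSE)
    }
  })
  recs <- with_seed(seed, lapply(params_by_arm, function(p) {
    n <- p$n_patients
    fu <- p$followup_months / 12
    t_death <- rweibull(n, p$death_shape, p$death_scale)
    t_dial <- rweibull(n, p$dialysis_shape, p$dialysis_scale)
    obs_death <- pmin(t_death, fu)
    # dialysis endpoint is censored at min(death, end of follow-up)
    obs_dial <- pmin(t_dial, obs_death)
    data.frame(
      arm = p$arm_label,
      time_death_yrs = obs_death,
      event_death = t_death <= fu,
      time_dialysis_yrs = obs_dial,
      event_dialysis = t_dial <= obs_death
    )
  }))
  records <- do.call(rbind, recs)
  records <- cbind(patient_id = seq_len(nrow(records)), records)
  rownames(records) <- NULL
  structure(list(records = records, seed = seed), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset> ", nrow(x$records), " patients, seed ", x$seed,
      "\n", sep = "")
  print(table(arm = x$records$arm,
              death = x$records$event_death,
              dialysis = x$records$event_dialysis))
  invisible(x)
}

#' Write / read a trial dataset as CSV
#'
#' Plain-text round trip with columns `patient_id`, `arm`,
#' `time_death_yrs`, `event_death`, `time_dialysis_yrs`, `event_dialysis`.
#'
#' @param dataset a `trial_dataset`.
#' @param path file path.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  write.csv(dataset$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param seed seed recorded on the re-read dataset (CSV files do not carry
#'   one).
#' @export
read_trial_csv <- function(path, seed = NA_integer_) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "time_death_yrs", "event_death",
            "time_dialysis_yrs", "event_dialysis")
  if (!all(need %in% names(rec))) {
    stop("trial CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rec$event_death <- as.logical(rec$event_death)
  rec$event_dialysis <- as.logical(rec$event_dialysis)
  structure(list(records = rec[need], seed = seed), class = "trial_dataset")
}
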