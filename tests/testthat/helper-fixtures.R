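# Shared fixtures built in code.

# Trial dataset from explicit times/events for one arm (the endpoint not
# under test is censored at the same times).
make_dataset <- function(time, event, arm = "sevelamer") {
  n <- length(time)
  rec <- data.frame(
    patient_id = seq_len(n),
    arm = arm,
    time_death_yrs = time,
    event_death = as.logical(event),
    time_dialysis_yrs = time,
    event_dialysis = FALSE
  )
  structure(list(records = rec, seed = 1L), class = "trial_dataset")
}

# Constant-hazard schedule from annual hazards.
const_schedule <- function(h_death, h_dial, cycles, arm = "sevelamer") {
  build_transition_schedule(
    hazard_spec("exponential", c(rate = max(h_death, 1e-300))),
    hazard_spec("exponential", c(rate = max(h_dial, 1e-300))),
    cycles, arm_label = arm
  )
}

# Bare cohort trace from an occupancy matrix.
make_trace <- function(occupancy, arm = "sevelamer") {
  structure(list(arm_label = arm, cycles = nrow(occupancy) - 1,
                 occupancy = occupancy),
            class = "cohort_trace")
}

# Bare PSA result from a draws data.frame.
make_psa <- function(draws) {
  structure(list(draws = draws, n_sims = nrow(draws), seed = 1L),
            class = "psa_result")
}

base_outcome <- function(cost, ly, qaly, arm = "sevelamer") {
  structure(list(arm_label = arm, cost_rm = cost, ly = ly, qaly = qaly,
                 cost_rm_undisc = cost, ly_undisc = ly,
                 qaly_undisc = qaly),
            class = "strategy_outcome")
}
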