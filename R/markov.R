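#' Propagate a cohort through the three-state model
#'
#' Deterministic cohort-expectation engine: the whole cohort enters in the
#' predialysis state and the occupancy vector is multiplied by the cycle's
#' transition matrix, `occupancy(t+1) = occupancy(t) %*% matrix(t)`.
#'
#' @param schedule a `transition_schedule`.
#' @param n_cycles number of cycles to run (default: all cycles the
#'   schedule covers; must not exceed them).
#' @return a `cohort_trace`: `arm_label`, `cycles`, and `occupancy`, an
#'   `(n_cycles + 1) x 3` matrix of state proportions with row `t + 1`
#'   holding occupancy at the start of cycle `t` (row 1 = `(1, 0, 0)`).
#' @export
run_cohort <- function(schedule, n_cycles = schedule$cycles) {
  stopifnot(inherits(schedule, "transition_schedule"))
  if (n_cycles > schedule$cycles) {
    stop("schedule covers ", schedule$cycles, " cycles; ", n_cycles,
         " requested", call. = FALSE)
  }
  occ <- matrix(0, n_cycles + 1, 3, dimnames = list(NULL, .states))
  occ[1, ] <- c(1, 0, 0)
  for (t in seq_len(n_cycles)) {
    occ[t + 1, ] <- occ[t, ] %*% schedule$matrices[, , t]
  }
  structure(list(arm_label = schedule$arm_label, cycles = n_cycles,
                 occupancy = occ),
            class = "cohort_trace")
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_patients` individual trajectories by categorical draws from
#' the same transition matrices and returns the empirical occupancy. This
#' exists to validate [run_cohort] (whose trace is the exact expectation of
#' this simulation); the economics always use the deterministic engine.
#'
#' @inheritParams run_cohort
#' @param n_patients number of simulated patients.
#' @param seed integer seed.
#' @return a `cohort_trace` of empirical state proportions.
#' @export
microsim_oracle <- function(schedule, n_patients, n_cycles = schedule$cycles,
                            seed = 20130919) {
  stopifnot(inherits(schedule, "transition_schedule"), n_patients >= 1)
  if (n_cycles > schedule$cycles) {
    stop("schedule covers ", schedule$cycles, " cycles; ", n_cycles,
         " requested", call. = FALSE)
  }
  occ <- matrix(0, n_cycles + 1, 3, dimnames = list(NULL, .states))
  with_seed(seed, {
    state <- rep.int(1L, n_patients)
    occ[1, ] <- tabulate(state, 3) / n_patients
    for (t in seq_len(n_cycles)) {
      p <- schedule$matrices[, , t]
      u <- runif(n_patients)
      new <- state
      for (s in 1:2) {
        idx <- which(state == s)
        if (length(idx)) {
          cp <- cumsum(p[s, ])
          new[idx] <- 1L + (u[idx] > cp[1]) + (u[idx] > cp[2])
        }
      }
      state <- new
      occ[t + 1, ] <- tabulate(state, 3) / n_patients
    }
  })
  structure(list(arm_label = schedule$arm_label, cycles = n_cycles,
                 occupancy = occ),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> arm ", x$arm_label %||% "?", ", ", x$cycles,
      " cycles\n", sep = "")
  show <- unique(pmin(c(0, 1, 2, 5, 10, x$cycles), x$cycles))
  print(round(cbind(cycle = show, x$occupancy[show + 1, , drop = FALSE]), 4))
  invisible(x)
}

#' Long-format export of a cohort trace
#'
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @return data.frame with columns `cycle`, `state`, `proportion`, `arm`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(
    cycle = rep(0:x$cycles, times = 3),
    state = rep(.states, each = x$cycles + 1),
    proportion = as.vector(x$occupancy),
    arm = x$arm_label %||% NA_character_
  )
}
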