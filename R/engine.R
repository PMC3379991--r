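# Markov cohort engine: state spaces for the chemotherapy-alone model "P"
# (3 states) and the cetuximab model "C" (11 states, with adverse-event
# timing rules), per-cycle transition matrices and the cohort run.

#' Build the state space for one treatment arm
#'
#' Arm `"P"` (platinum-based chemotherapy alone) has three states: Stable,
#' Progression, Dead. Arm `"C"` (cetuximab plus chemotherapy) has eleven:
#' stable with no AE, stable with mild AE, one stable state per severe
#' adverse event (allergy/anaphylaxis, dyspnea, hypotension, skin
#' reactions, anorexia, hypomagnesemia, sepsis), progression and dead.
#' Cetuximab is received only in the stable no-AE and mild-AE states:
#' a severe AE or progression stops cetuximab.
#'
#' @param arm `"P"` or `"C"`.
#' @return An object of class `state_space` with `states` (names),
#'   and logical flags `absorbing`, `on_cetuximab`, `is_progression`,
#'   `is_stable`, plus `ae_tag` (AE name or `NA`).
#' @export
build_state_space <- function(arm = c("P", "C")) {
  arm <- match.arg(arm)
  if (arm == "P") {
    states <- c("stable", "progression", "dead")
    ae_tag <- c(NA, NA, NA)
    on_cet <- c(FALSE, FALSE, FALSE)
  } else {
    severe <- setdiff(ae_names(), "mild")
    states <- c("stable_no_ae", "stable_mild_ae",
                paste0("stable_", severe), "progression", "dead")
    ae_tag <- c(NA, "mild", severe, NA, NA)
    on_cet <- states %in% c("stable_no_ae", "stable_mild_ae")
  }
  structure(list(
    arm = arm, states = states,
    absorbing = states == "dead",
    on_cetuximab = on_cet,
    is_progression = states == "progression",
    is_stable = !(states %in% c("progression", "dead")),
    ae_tag = ae_tag
  ), class = "state_space")
}

#' Per-cycle transition matrix
#'
#' Assembles the row-stochastic transition matrix for one cycle. All stable
#' states share the cycle's stable-to-progression probability and the
#' background death probability; within a cycle, adverse-event moves are
#' resolved first (at their marginal probabilities), then progression, then
#' background death, combined multiplicatively. For arm C, transitions into
#' the mild-AE state and the four first-month severe-AE states are only
#' possible at cycle 1; anorexia, hypomagnesemia and sepsis can occur from
#' any cetuximab-receiving state at any cycle. Severe-AE states and
#' progression receive no further cetuximab and admit no further AE moves.
#'
#' @param space a `state_space`.
#' @param schedule a `transition_schedule` for the arm.
#' @param params a `cea_parameters` object.
#' @param cycle cycle index in `1..schedule$cycles`.
#' @return A row-stochastic matrix with dimnames `space$states`.
#' @export
transition_matrix_at <- function(space, schedule, params, cycle) {
  stopifnot(cycle >= 1, cycle <= schedule$cycles)
  p_sp <- schedule$p_stable_prog[cycle]
  q <- schedule$p_stable_dead[cycle]
  p_pd <- schedule$p_prog_dead[cycle]
  n <- length(space$states)
  M <- matrix(0, n, n, dimnames = list(space$states, space$states))

  stay_alive <- (1 - p_sp) * (1 - q)  # retention among stable states
  for (i in seq_len(n)) {
    st <- space$states[i]
    if (space$absorbing[i]) { M[i, i] <- 1; next }
    if (space$is_progression[i]) {
      M[i, "dead"] <- p_pd
      M[i, i] <- 1 - p_pd
      next
    }
    # stable state: AE moves first (arm C, cetuximab-receiving states only)
    a <- numeric(0)
    if (space$arm == "C" && space$on_cetuximab[i]) {
      avail <- ongoing_aes()
      if (cycle == 1 && st == "stable_no_ae")
        avail <- c(first_month_aes(), avail)
      avail <- setdiff(avail, space$ae_tag[i])  # no self re-entry
      a <- vapply(params$adverse_events[avail], `[[`, 0, "monthly_prob")
      names(a) <- avail
    }
    tot_a <- sum(a)
    if (tot_a > 1)
      stop("adverse-event probabilities from state ", st, " at cycle ",
           cycle, " sum to ", tot_a, " > 1")
    for (ae in names(a)) {
      dest <- if (ae == "mild") "stable_mild_ae" else paste0("stable_", ae)
      M[i, dest] <- M[i, dest] + a[[ae]] * stay_alive
    }
    M[i, i] <- M[i, i] + (1 - tot_a) * stay_alive
    M[i, "progression"] <- p_sp
    M[i, "dead"] <- (1 - p_sp) * q
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9))
    stop("row sums differ from 1 in rows: ",
         paste(space$states[abs(rs - 1) > 1e-9], collapse = ", "))
  M
}

#' Run the cohort through the model horizon
#'
#' Starts the whole cohort in the first state (Stable / stable with no AE
#' by default), applies the per-cycle transition matrices, and records the
#' state occupancy at every time point `0..horizon` plus the per-cycle
#' entrants into each state (new arrivals, used for one-time costs).
#'
#' @param space a `state_space`.
#' @param schedule a `transition_schedule` covering the horizon.
#' @param params a `cea_parameters` object.
#' @param horizon cycles to run (default: the schedule length).
#' @param initial optional initial occupancy vector (must sum to 1).
#' @return An object of class `cohort_trace`: `occupancy`
#'   (`(horizon+1) x n_states`), `entrants` (`horizon x n_states`,
#'   row `t` = inflow during cycle `t`), and the `space`.
#' @export
run_cohort <- function(space, schedule, params,
                       horizon = schedule$cycles, initial = NULL) {
  stopifnot(horizon <= schedule$cycles)
  n <- length(space$states)
  if (is.null(initial)) {
    initial <- numeric(n); initial[1] <- 1
  }
  stopifnot(length(initial) == n, abs(sum(initial) - 1) < 1e-9)

  occ <- matrix(0, horizon + 1, n, dimnames = list(0:horizon, space$states))
  ent <- matrix(0, horizon, n, dimnames = list(1:horizon, space$states))
  occ[1, ] <- initial
  for (t in seq_len(horizon)) {
    M <- transition_matrix_at(space, schedule, params, t)
    v <- occ[t, ]
    occ[t + 1, ] <- v %*% M
    Moff <- M; diag(Moff) <- 0
    ent[t, ] <- v %*% Moff
    if (abs(sum(occ[t + 1, ]) - 1) > 1e-9 || any(occ[t + 1, ] < -1e-12))
      stop("simulation integrity failure at cycle ", t)
  }
  structure(list(occupancy = occ, entrants = ent, space = space,
                 horizon = as.integer(horizon)),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  last <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("cohort_trace (arm %s): %d cycles, %d states; alive at end %.4f\n",
              x$space$arm, x$horizon, length(x$space$states),
              1 - last[["dead"]]))
  invisible(x)
}

#' Export a cohort trace as tidy CSV
#'
#' Long format: `cycle` (time point, 0..horizon), `state`, `occupancy`,
#' `entrants` (NA at time 0).
#'
#' @param trace a `cohort_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  h <- trace$horizon
  d <- data.frame(
    cycle = rep(0:h, times = ncol(trace$occupancy)),
    state = rep(colnames(trace$occupancy), each = h + 1),
    occupancy = as.vector(trace$occupancy),
    entrants = as.vector(rbind(NA, trace$entrants)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
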