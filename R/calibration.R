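# Survival-to-transition-probability calibration: Kaplan-Meier style
# conditional event probabilities, other-cause splitting, per-cycle
# calibration of progression mortality against the OS curve, and year-3
# extrapolation at the year-2 average.

#' Conditional monthly event probabilities from a survival curve
#'
#' `p[t] = 1 - S(t)/S(t-1)` for `t = 1..T`; once the curve reaches 0 the
#' conditional probability is 1 by convention.
#'
#' @param curve a [survival_curve].
#' @return numeric vector of length `T`.
#' @export
conditional_event_probs <- function(curve) {
  s <- curve$surv
  n <- length(s)
  prev <- s[-n]; cur <- s[-1]
  p <- ifelse(prev > 0, 1 - cur / prev, 1)
  pmin(pmax(p, 0), 1)
}

#' Split other-cause mortality out of an all-cause probability stream
#'
#' Removes the background (life-table) component from a monthly all-cause
#' event probability under within-cycle independence:
#' `p_disease[t] = 1 - (1 - p_all[t]) / (1 - p_background[t])`, floored at 0
#' when background exceeds the all-cause stream.
#'
#' @param all_cause_p monthly all-cause probabilities.
#' @param background_p monthly background probability (scalar or vector).
#' @return disease-specific monthly probabilities.
#' @export
split_other_cause <- function(all_cause_p, background_p) {
  if (any(background_p >= 1)) stop("degenerate background probability of 1")
  pmin(pmax(1 - (1 - all_cause_p) / (1 - background_p), 0), 1)
}

#' Calibrate progression-to-death probabilities against the OS curve
#'
#' Forward-simulates the three-state chain (stable, progression, dead)
#' cycle by cycle and, at each cycle, solves in closed form for the single
#' unknown `p_prog_dead[t]` that makes total simulated survival equal
#' `os[t]` exactly, given the current state occupancies. The stable state
#' loses mass to progression at the PFS-derived disease-specific rate and
#' to death at the background rate (applied after progression,
#' multiplicatively). Probabilities are clipped to `[0, 1]` and clipping
#' cycles recorded; if progression occupancy is (numerically) zero while
#' the OS target still requires excess deaths, the probability is set to 1
#' with a warning.
#'
#' Cycle 1 deserves a note: with the whole cohort starting stable and all
#' disease mortality routed through progression, the model cannot kill
#' anyone in month 1 beyond background mortality, so an OS curve that
#' drops faster than background in its first month is unmatchable there
#' (the cohort catches up from cycle 2 on). Such cycles appear in the
#' `clipped` log and in the `residual` vector.
#'
#' @param os_curve,pfs_curve [survival_curve]s on the same grid, with
#'   `pfs <= os` pointwise.
#' @param background_p monthly background mortality (scalar).
#' @param horizon number of cycles to calibrate (at most the curve length).
#' @param warn emit a warning when the OS target requires progression
#'   deaths that the current progression occupancy cannot supply.
#' @return list with `p_stable_prog`, `p_stable_dead`, `p_prog_dead`
#'   (length `horizon`), `clipped` (integer cycles where the solved
#'   probability fell outside `[0, 1]`) and `residual` (achieved minus
#'   target survival per cycle; 0 wherever the solve was feasible).
#' @export
calibrate_progression_mortality <- function(os_curve, pfs_curve, background_p,
                                            horizon = length(os_curve$surv) - 1,
                                            warn = TRUE) {
  stopifnot(length(os_curve$surv) == length(pfs_curve$surv),
            horizon <= length(os_curve$surv) - 1)
  if (any(pfs_curve$surv > os_curve$surv + 1e-9))
    stop("PFS must not exceed OS pointwise")
  os <- os_curve$surv; pfs <- pfs_curve$surv
  q <- background_p

  p_pfs <- conditional_event_probs(pfs_curve)[seq_len(horizon)]
  p_sp <- split_other_cause(p_pfs, q)
  p_sd <- rep(q, horizon)

  p_pd <- numeric(horizon)
  clipped <- integer(0)
  residual <- numeric(horizon)
  s <- 1; g <- 0  # stable, progression occupancy
  for (t in seq_len(horizon)) {
    inflow <- s * p_sp[t]
    s_next <- s * (1 - p_sp[t]) * (1 - q)
    g_target <- max(os[t + 1] - s_next, 0)
    pool <- g + inflow
    if (g > 1e-15) {
      p_raw <- (pool - g_target) / g
    } else if (abs(pool - g_target) <= 1e-12) {
      p_raw <- 0
    } else {
      # empty progression pool: the target is unreachable either way
      p_raw <- if (pool > g_target) Inf else -Inf
      if (warn && pool > g_target)
        warning("cycle ", t, ": OS target requires progression deaths but ",
                "the progression pool is empty; probability set to 1")
    }
    if (p_raw < -1e-12 || p_raw > 1 + 1e-12) clipped <- c(clipped, t)
    p <- min(max(p_raw, 0), 1)
    p_pd[t] <- p
    g <- pool - g * p
    residual[t] <- (s_next + g) - os[t + 1]
    s <- s_next
  }
  list(p_stable_prog = p_sp, p_stable_dead = p_sd, p_prog_dead = p_pd,
       clipped = clipped, residual = residual)
}

#' Extrapolate the third model year at the second-year average
#'
#' For each probability stream, cycles beyond the observed follow-up are
#' set to the arithmetic mean of cycles 13..24 of that stream (the trial's
#' second year). Cycles 1..24 are left untouched.
#'
#' @param schedule a `transition_schedule` covering at least 24 cycles.
#' @param horizon total cycles required after extrapolation.
#' @return The extended `transition_schedule`.
#' @export
extrapolate_year3 <- function(schedule, horizon = 36L) {
  if (schedule$cycles < 24)
    stop("schedule must cover at least 24 cycles before extrapolation")
  if (horizon <= schedule$cycles) return(schedule)
  extra <- (schedule$cycles + 1):horizon
  for (f in c("p_stable_prog", "p_stable_dead", "p_prog_dead")) {
    m <- mean(schedule[[f]][13:24])
    schedule[[f]] <- c(schedule[[f]], rep(m, length(extra)))
  }
  schedule$cycles <- as.integer(horizon)
  schedule
}

#' Build the per-arm transition schedule from survival inputs
#'
#' Derives the time-dependent monthly transition probabilities for one arm:
#' stable-to-progression from the PFS curve (background mortality split
#' out), stable-to-dead from the life table only (all disease mortality is
#' routed through progression), progression-to-dead calibrated so the
#' simulated total survival matches the OS curve over the observed
#' follow-up window, and cycles beyond that window extrapolated at the
#' year-2 average via [extrapolate_year3()].
#'
#' @param os_curve,pfs_curve [survival_curve]s.
#' @param background_p monthly background mortality.
#' @param horizon model horizon in cycles.
#' @param followup cycles of observed follow-up used for calibration
#'   (default 24); beyond it probabilities are extrapolated.
#' @return An object of class `transition_schedule`: vectors
#'   `p_stable_prog`, `p_stable_dead`, `p_prog_dead` of length `horizon`,
#'   the cycle count, and the calibration clipping log.
#' @export
build_schedule <- function(os_curve, pfs_curve, background_p, horizon = 36L,
                           followup = 24L, warn = FALSE) {
  window <- min(horizon, followup, length(os_curve$surv) - 1)
  cal <- calibrate_progression_mortality(os_curve, pfs_curve, background_p,
                                         horizon = window, warn = warn)
  schedule <- structure(
    list(p_stable_prog = cal$p_stable_prog,
         p_stable_dead = cal$p_stable_dead,
         p_prog_dead = cal$p_prog_dead,
         cycles = as.integer(window), clipped = cal$clipped,
         residual = cal$residual),
    class = "transition_schedule")
  if (horizon > window) schedule <- extrapolate_year3(schedule, horizon)
  stopifnot(all(schedule$p_stable_prog + schedule$p_stable_dead <= 1 + 1e-12))
  schedule
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("transition_schedule: %d cycles%s\n", x$cycles,
              if (length(x$clipped)) paste0(" (clipped at cycles ",
                                            paste(x$clipped, collapse = ","),
                                            ")") else ""))
  cat(sprintf("  p(stable->prog) %.4f..%.4f, p(stable->dead) %.5f, p(prog->dead) %.4f..%.4f\n",
              min(x$p_stable_prog), max(x$p_stable_prog),
              x$p_stable_dead[1], min(x$p_prog_dead), max(x$p_prog_dead)))
  invisible(x)
}

#' Round-trip a transition schedule through tidy CSV
#'
#' Long format: columns `cycle`, `from_state`, `to_state`, `probability`.
#'
#' @param schedule a `transition_schedule`.
#' @param path CSV path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a `transition_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  d <- data.frame(
    cycle = rep(seq_len(schedule$cycles), 3),
    from_state = rep(c("stable", "stable", "progression"),
                     each = schedule$cycles),
    to_state = rep(c("progression", "dead", "dead"), each = schedule$cycles),
    probability = c(schedule$p_stable_prog, schedule$p_stable_dead,
                    schedule$p_prog_dead))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  d <- utils::read.csv(path)
  pick <- function(from, to)
    d$probability[d$from_state == from & d$to_state == to][order(
      d$cycle[d$from_state == from & d$to_state == to])]
  structure(list(p_stable_prog = pick("stable", "progression"),
                 p_stable_dead = pick("stable", "dead"),
                 p_prog_dead = pick("progression", "dead"),
                 cycles = max(d$cycle), clipped = integer(0)),
            class = "transition_schedule")
}
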