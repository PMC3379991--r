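# Top-level model: calibrates both arms' transition schedules from the
# survival inputs, runs both cohorts, values them and forms the ICER.

#' Fit and evaluate the cost-effectiveness model
#'
#' The main entry point. Generates (or accepts) the per-arm survival
#' curves, derives each arm's time-dependent transition schedule
#' (progression from PFS with background mortality split out; background
#' stable-to-death from the life table; progression-to-death calibrated so
#' simulated survival matches the OS curve over the observed follow-up;
#' year-3 extrapolation at the year-2 average), runs the 3-state
#' chemotherapy-alone cohort ("P") and the 11-state cetuximab cohort ("C")
#' with the adverse-event timing rules, and accumulates discounted,
#' half-cycle-corrected costs, QALYs and life-years into the incremental
#' comparison.
#'
#' @param params a `cea_parameters` object (see [default_parameters()],
#'   [load_parameters()]).
#' @param curves survival inputs as returned by [make_fixture()]; `NULL`
#'   (default) generates them from `params$survival`.
#' @param horizon model horizon in months (24 to 60; the base case is 36).
#' @param price_multiplier multiplies the cetuximab unit price per mg (and
#'   any explicit dosing-cost overrides), for price sensitivity analyses.
#' @param progression_multiplier multiplies the arm-C monthly
#'   stable-to-progression probabilities, for progression-risk sensitivity
#'   analyses.
#' @return An object of class `cea_model` containing the parameters,
#'   curves, per-arm schedules and traces, per-arm `econ_result`s and the
#'   `ce_comparison`.
#' @examples
#' m <- cea_model()
#' print(m)
#' summary(m)
#' @export
cea_model <- function(params = default_parameters(), curves = NULL,
                      horizon = params$settings$horizon,
                      price_multiplier = 1, progression_multiplier = 1) {
  validate_parameters(params)
  if (horizon < 24 || horizon > 60)
    stop("horizon must be between 24 and 60 months")
  params$settings$horizon <- as.integer(horizon)
  followup <- min(params$settings$km_followup, horizon)
  if (is.null(curves)) curves <- make_fixture(params, horizon = followup)

  if (price_multiplier != 1) {
    co <- params$costs
    co$unit_price_per_mg <- co$unit_price_per_mg * price_multiplier
    for (f in c("cetuximab_dose_month1", "cetuximab_dose_later"))
      if (!is.na(co[[f]])) co[[f]] <- co[[f]] * price_multiplier
    params$costs <- co
  }

  q <- curves$life_table$monthly
  sched_P <- build_schedule(curves$os_P, curves$pfs_P, q, horizon, followup)
  sched_C <- build_schedule(curves$os_C, curves$pfs_C, q, horizon, followup)
  if (progression_multiplier != 1) {
    sched_C$p_stable_prog <- pmin(pmax(
      sched_C$p_stable_prog * progression_multiplier, 0), 1)
  }

  space_P <- build_state_space("P")
  space_C <- build_state_space("C")
  trace_P <- run_cohort(space_P, sched_P, params)
  trace_C <- run_cohort(space_C, sched_C, params)
  res_P <- accumulate(trace_P, params, sched_P)
  res_C <- accumulate(trace_C, params, sched_C)

  structure(list(
    params = params, curves = curves, horizon = as.integer(horizon),
    price_multiplier = price_multiplier,
    progression_multiplier = progression_multiplier,
    schedules = list(P = sched_P, C = sched_C),
    traces = list(P = trace_P, C = trace_C),
    results = list(P = res_P, C = res_C),
    comparison = compare(res_C, res_P),
    call = match.call()
  ), class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cmp <- x$comparison
  cat("Markov cohort cost-effectiveness model, cetuximab + platinum",
      "chemotherapy vs platinum chemotherapy (recurrent/metastatic HNSCC)\n")
  cat(sprintf("  horizon %d months, discount %.0f%%/yr\n", x$horizon,
              100 * x$params$settings$annual_discount))
  for (arm in c("P", "C")) {
    r <- x$results[[arm]]
    cat(sprintf("  arm %s: cost $%s, %.4f QALY, %.4f LY\n", arm,
                format(round(r$cost), big.mark = ","), r$qaly, r$ly))
  }
  print(cmp)
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  structure(list(model = object), class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nDiscounted cost components (CAD):\n")
  tab <- rbind(P = m$results$P$cost_components,
               C = m$results$C$cost_components)
  print(round(tab))
  cat("\nUndiscounted totals:\n")
  for (arm in c("P", "C")) {
    r <- m$results[[arm]]
    cat(sprintf("  arm %s: cost $%s, %.4f QALY, %.4f LY\n", arm,
                format(round(r$cost0), big.mark = ","), r$qaly0, r$ly0))
  }
  surv <- vapply(c("P", "C"), function(a)
    1 - m$traces[[a]]$occupancy[m$horizon + 1, "dead"], 0)
  cat(sprintf("\nModel survival at %d months: arm P %.3f, arm C %.3f\n",
              m$horizon, surv["P"], surv["C"]))
  clips <- vapply(m$schedules, function(s) length(s$clipped), 0L)
  if (any(clips > 0))
    cat("Calibration clipping at cycles:",
        paste(names(clips)[clips > 0], collapse = ", "), "\n")
  invisible(x)
}

#' Extract the ICER from a fitted model
#'
#' @param model a `cea_model`.
#' @param per `"qaly"` or `"ly"`.
#' @return the incremental cost-effectiveness ratio (CAD per QALY or per
#'   life-year), or `NA` under dominance.
#' @export
icer <- function(model, per = c("qaly", "ly")) {
  per <- match.arg(per)
  if (per == "qaly") model$comparison$icer_qaly else model$comparison$icer_ly
}

#' Plot method for the fitted model
#'
#' `type = "trace"` draws the state-occupancy curves of both arms (stable,
#' progression, dead aggregates); `type = "survival"` overlays the input
#' OS/PFS curves with the model's simulated survival.
#'
#' @param x a `cea_model`.
#' @param type `"trace"` or `"survival"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cea_model <- function(x, type = c("trace", "survival"), ...) {
  type <- match.arg(type)
  h <- x$horizon
  if (type == "trace") {
    agg <- function(trace) {
      sp <- trace$space
      cbind(stable = rowSums(trace$occupancy[, sp$is_stable, drop = FALSE]),
            progression = trace$occupancy[, "progression"],
            dead = trace$occupancy[, "dead"])
    }
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
    for (arm in c("P", "C")) {
      graphics::matplot(0:h, agg(x$traces[[arm]]), type = "l", lty = 1,
                        col = c("forestgreen", "orange", "black"),
                        xlab = "month", ylab = "occupancy",
                        main = paste("arm", arm), ...)
      graphics::legend("right", c("stable", "progression", "dead"),
                       col = c("forestgreen", "orange", "black"), lty = 1,
                       bty = "n")
    }
  } else {
    alive <- function(arm) 1 - x$traces[[arm]]$occupancy[, "dead"]
    graphics::matplot(0:h, cbind(alive("P"), alive("C")), type = "l",
                      lty = 1, col = c("grey40", "firebrick"),
                      xlab = "month", ylab = "survival", ylim = c(0, 1), ...)
    for (arm in c("P", "C")) {
      cu <- x$curves[[paste0("os_", arm)]]
      graphics::lines(cu$times, cu$surv, lty = 2,
                      col = if (arm == "P") "grey40" else "firebrick")
      cu <- x$curves[[paste0("pfs_", arm)]]
      graphics::lines(cu$times, cu$surv, lty = 3,
                      col = if (arm == "P") "grey40" else "firebrick")
    }
    graphics::legend("topright",
                     c("model alive P", "model alive C",
                       "input OS (dashed), PFS (dotted)"),
                     col = c("grey40", "firebrick", "black"),
                     lty = c(1, 1, 2), bty = "n")
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis via `simulate()`
#'
#' Delegates to [run_psa()]: `nsim` joint parameter draws from the declared
#' Beta/lognormal distributions, each re-running both arms.
#'
#' @param object a `cea_model`.
#' @param nsim number of PSA replicates.
#' @param seed master seed for the per-parameter random substreams.
#' @param ... unused.
#' @return A `cea_psa` object (see [run_psa()]).
#' @export
simulate.cea_model <- function(object, nsim = 1000, seed = 1L, ...) {
  run_psa(object, n = nsim, seed = seed)
}
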