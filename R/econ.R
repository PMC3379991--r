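# Economic valuation: state utilities with severe-AE decrements and
# duration clocks, cetuximab dosing costs from the dosing rule, per-cycle
# cost streams, half-cycle-corrected discounted accumulation, and the
# incremental comparison.

#' Utility of a health state
#'
#' Stable with no or mild AE yields the baseline stable utility (0.65 in
#' the base case), progression 0.52, dead 0. A stable state with a severe
#' AE yields `stable * (1 - r)` — the multiplicative decrement convention —
#' while the time since state entry is within the AE's disutility duration,
#' and the full stable utility afterwards (sepsis carries a lifetime
#' decrement and never reverts).
#'
#' @param state a state name from [build_state_space()].
#' @param params a `cea_parameters` object.
#' @param months_since_entry months elapsed since entering the state.
#' @return utility per month of occupancy.
#' @export
state_utility <- function(state, params, months_since_entry = 0) {
  u <- params$utilities
  if (state == "dead") return(u$death)
  if (state == "progression") return(u$progression)
  if (state %in% c("stable", "stable_no_ae", "stable_mild_ae"))
    return(u$stable)
  ae <- sub("^stable_", "", state)
  if (!ae %in% names(params$adverse_events))
    stop("unknown state: ", state)
  prof <- params$adverse_events[[ae]]
  if (months_since_entry < prof$disutility_duration)
    u$stable * (1 - prof$utility_reduction)
  else
    u$stable
}

#' Monthly cetuximab cost components from the dosing rule
#'
#' Month 1 on therapy: a 400 mg/m2 loading dose plus three weekly
#' 250 mg/m2 doses; later months: four weekly 250 mg/m2 doses. Drug cost is
#' milligrams times the unit price; infusion chair time is 2 h for the
#' loading dose and 1 h per weekly dose at the chair rate; pharmacy
#' preparation is a flat monthly fee. Explicit `cetuximab_dose_*` /
#' `infusion_*` overrides on the cost schedule (used by the PSA) take
#' precedence over the recomputation.
#'
#' @param month_on_therapy ordinal month on cetuximab (>= 1).
#' @param costs the `costs` element of a `cea_parameters` object.
#' @return list with `drug`, `infusion`, `prep` and `total` (CAD/month).
#' @export
cetuximab_monthly_cost <- function(month_on_therapy, costs) {
  stopifnot(month_on_therapy >= 1)
  first <- month_on_therapy == 1
  mg <- if (first)
    (costs$loading_dose_mg_m2 + 3 * costs$weekly_dose_mg_m2) * costs$bsa
  else
    4 * costs$weekly_dose_mg_m2 * costs$bsa
  hours <- if (first) 2 + 3 * 1 else 4
  drug <- if (first && !is.na(costs$cetuximab_dose_month1))
    costs$cetuximab_dose_month1
  else if (!first && !is.na(costs$cetuximab_dose_later))
    costs$cetuximab_dose_later
  else mg * costs$unit_price_per_mg
  infusion <- if (first && !is.na(costs$infusion_month1))
    costs$infusion_month1
  else if (!first && !is.na(costs$infusion_later))
    costs$infusion_later
  else hours * costs$chair_rate
  list(drug = drug, infusion = infusion, prep = costs$pharmacy_prep,
       total = drug + infusion + costs$pharmacy_prep)
}

# Per-cycle retention probability shared by all stable states (used to
# decompose severe-AE occupancy into entry cohorts).
stable_retention <- function(schedule, horizon) {
  (1 - schedule$p_stable_prog[seq_len(horizon)]) *
    (1 - schedule$p_stable_dead[seq_len(horizon)])
}

# Utility-weighted alive occupancy at each time point 0..horizon, with
# per-entry-cohort disutility clocks for the severe-AE states.
utility_occupancy <- function(trace, params, schedule) {
  space <- trace$space
  occ <- trace$occupancy
  h <- trace$horizon
  u_s <- params$utilities$stable
  w <- numeric(h + 1)
  plain_stable <- space$is_stable & (is.na(space$ae_tag) |
                                       space$ae_tag == "mild")
  w <- w + occ[, plain_stable, drop = FALSE] %*% rep(u_s, sum(plain_stable))
  w <- as.vector(w) + occ[, "progression"] * params$utilities$progression

  severe <- which(space$is_stable & !is.na(space$ae_tag) &
                    space$ae_tag != "mild")
  if (length(severe)) {
    r <- stable_retention(schedule, h)
    R <- cumprod(c(1, r))  # R[t+1] = retention product through cycle t
    for (i in severe) {
      prof <- params$adverse_events[[space$ae_tag[i]]]
      ent <- trace$entrants[, space$states[i]]
      u_red <- u_s * (1 - prof$utility_reduction)
      for (e in which(ent > 0)) {
        tt <- e:h
        coh <- ent[e] * R[tt + 1] / R[e + 1]
        uu <- ifelse(tt - e < prof$disutility_duration, u_red, u_s)
        w[tt + 1] <- w[tt + 1] + coh * uu
      }
    }
  }
  w
}

# Trapezoidal (half-cycle) or end-of-cycle per-cycle accrual weights for a
# time-point-indexed stream x[0..h].
cycle_average <- function(x, half_cycle) {
  h <- length(x) - 1
  if (half_cycle) (x[-(h + 1)] + x[-1]) / 2 else x[-1]
}

#' Per-cycle cost streams for a cohort trace
#'
#' Applies the cost schedule to the trace, component by component:
#' chemotherapy accrues to all stable-state occupancy during the first
#' `chemo_max_months` calendar cycles (both arms); cetuximab drug, infusion
#' and pharmacy-preparation costs accrue to cetuximab-receiving occupancy
#' at the month-1 rate in cycle 1 and the later rate thereafter; the
#' mild-AE consultation fee is charged once to mild-state entrants and the
#' monthly mild-AE management costs accrue to mild-state occupancy; each
#' severe AE carries a one-time hospitalization cost charged to entrants of
#' its state; and the progression state accrues the monthly hospice cost.
#' Recurring components use trapezoidal (half-cycle) occupancy averages
#' when `settings$half_cycle` is on; one-time components are charged at
#' the entry cycle without half-cycle correction.
#'
#' @param trace a `cohort_trace`.
#' @param params a `cea_parameters` object.
#' @return matrix `horizon x component` of undiscounted CAD per cycle, with
#'   components `chemo`, `cetux_drug`, `cetux_infusion`, `cetux_prep`,
#'   `mild_ae`, `severe_ae`, `progression`.
#' @export
cycle_costs <- function(trace, params) {
  space <- trace$space
  occ <- trace$occupancy
  ent <- trace$entrants
  h <- trace$horizon
  co <- params$costs
  hc <- params$settings$half_cycle
  cyc <- seq_len(h)

  comp <- matrix(0, h, 7, dimnames = list(
    cyc, c("chemo", "cetux_drug", "cetux_infusion", "cetux_prep",
           "mild_ae", "severe_ae", "progression")))

  stable_occ <- rowSums(occ[, space$is_stable, drop = FALSE])
  stable_avg <- cycle_average(stable_occ, hc)
  comp[, "chemo"] <- ifelse(cyc <= params$settings$chemo_max_months,
                            co$chemo_monthly_total, 0) * stable_avg

  if (any(space$on_cetuximab)) {
    cet_occ <- rowSums(occ[, space$on_cetuximab, drop = FALSE])
    cet_avg <- cycle_average(cet_occ, hc)
    rates <- lapply(cyc, cetuximab_monthly_cost, costs = co)
    comp[, "cetux_drug"] <- vapply(rates, `[[`, 0, "drug") * cet_avg
    comp[, "cetux_infusion"] <- vapply(rates, `[[`, 0, "infusion") * cet_avg
    comp[, "cetux_prep"] <- vapply(rates, `[[`, 0, "prep") * cet_avg

    mild_avg <- cycle_average(occ[, "stable_mild_ae"], hc)
    comp[, "mild_ae"] <- co$mild_ae_consult * ent[, "stable_mild_ae"] +
      (co$mild_ae_monthly_antihistamine + co$mild_ae_monthly_skin) * mild_avg

    for (ae in setdiff(ae_names(), "mild")) {
      st <- paste0("stable_", ae)
      comp[, "severe_ae"] <- comp[, "severe_ae"] +
        params$adverse_events[[ae]]$management_cost * ent[, st]
    }
  }

  prog_avg <- cycle_average(occ[, "progression"], hc)
  comp[, "progression"] <- co$progression_monthly * prog_avg
  comp
}

#' Accumulate a trace into discounted totals
#'
#' Applies monthly discount factors `(1 + annual)^(-t/12)` at each cycle
#' `t` to the per-cycle cost components, quality-adjusted occupancy and
#' alive occupancy, and sums over the horizon. Life-years are discounted
#' alive occupancy-months divided by 12; QALYs use the utility-weighted
#' occupancy from the state utilities with severe-AE disutility clocks.
#' Undiscounted twins are reported alongside.
#'
#' @param trace a `cohort_trace`.
#' @param params a `cea_parameters` object.
#' @param schedule the arm's `transition_schedule` (needed for the
#'   severe-AE cohort decomposition).
#' @return An object of class `econ_result`: `arm`, `cost`, `qaly`, `ly`
#'   (discounted), `cost0`, `qaly0`, `ly0` (undiscounted), and
#'   `cost_components` (discounted CAD by component).
#' @export
accumulate <- function(trace, params, schedule) {
  h <- trace$horizon
  hc <- params$settings$half_cycle
  r <- params$settings$annual_discount
  v <- (1 + r)^(-(seq_len(h)) / 12)

  comp <- cycle_costs(trace, params)
  alive <- 1 - trace$occupancy[, "dead"]
  ly_cycle <- cycle_average(alive, hc) / 12
  w <- utility_occupancy(trace, params, schedule)
  qaly_cycle <- cycle_average(w, hc) / 12

  structure(list(
    arm = trace$space$arm,
    cost = sum(comp * v), qaly = sum(qaly_cycle * v), ly = sum(ly_cycle * v),
    cost0 = sum(comp), qaly0 = sum(qaly_cycle), ly0 = sum(ly_cycle),
    cost_components = colSums(comp * v),
    horizon = h
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("econ_result (arm %s, %d cycles): cost $%s, %.4f QALY, %.4f LY (discounted)\n",
              x$arm, x$horizon, format(round(x$cost), big.mark = ","),
              x$qaly, x$ly))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' Differences are intervention (arm C) minus comparator (arm P). The ICER
#' is reported when the QALY difference is positive; when the signs of the
#' cost and effect differences disagree the comparison is flagged
#' `dominant` (cheaper and more effective) or `dominated` (costlier and
#' less effective) and no ratio is formed; identical results are flagged
#' `undefined`.
#'
#' @param result_c,result_p `econ_result`s for the cetuximab and
#'   chemotherapy-alone arms.
#' @return An object of class `ce_comparison` with `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer_qaly`, `icer_ly`, `dominance`.
#' @export
compare <- function(result_c, result_p) {
  dc <- result_c$cost - result_p$cost
  dq <- result_c$qaly - result_p$qaly
  dl <- result_c$ly - result_p$ly
  eps <- 1e-12
  dominance <- if (dq > eps && dc < -eps) "dominant"
  else if (dq < -eps && dc > eps) "dominated"
  else if (abs(dq) <= eps && abs(dc) <= eps) "undefined"
  else "none"
  icer_q <- if (abs(dq) > eps) dc / dq else NA_real_
  icer_l <- if (abs(dl) > eps) dc / dl else NA_real_
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer_qaly = icer_q, icer_ly = icer_l,
                 dominance = dominance),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("incremental: cost $%s, %.4f QALY, %.4f LY\n",
              format(round(x$delta_cost), big.mark = ","),
              x$delta_qaly, x$delta_ly))
  if (x$dominance == "none") {
    cat(sprintf("ICER: $%s/QALY, $%s/LY\n",
                format(round(x$icer_qaly), big.mark = ","),
                format(round(x$icer_ly), big.mark = ",")))
  } else {
    cat("dominance:", x$dominance, "\n")
  }
  invisible(x)
}
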