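# Deterministic sensitivity analyses: one-way and two-way sweeps over the
# declared parameter ranges, bisection threshold search, and horizon
# variants.

# Re-run the full pipeline with a single parameter (or multiplier) changed.
rerun_with <- function(model, id, value) {
  if (id == "price_multiplier")
    return(cea_model(model$params, curves = model$curves,
                     horizon = model$horizon, price_multiplier = value,
                     progression_multiplier = model$progression_multiplier))
  if (id == "progression_risk_multiplier")
    return(cea_model(model$params, curves = model$curves,
                     horizon = model$horizon,
                     price_multiplier = model$price_multiplier,
                     progression_multiplier = value))
  params <- set_parameter(model$params, id, value)
  # survival/life-table parameters invalidate the cached curves
  curves <- if (id %in% c("sex_mix")) NULL else model$curves
  cea_model(params, curves = curves, horizon = model$horizon,
            price_multiplier = model$price_multiplier,
            progression_multiplier = model$progression_multiplier)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full pipeline at each grid value of one parameter, all else
#' held at the base case of `model`.
#'
#' @param model a fitted `cea_model` (the base case).
#' @param param a parameter id understood by the sweep machinery:
#'   `"annual_discount"`, `"wtp"`, `"sex_mix"`, `"utility_stable"`,
#'   `"utility_progression"`, `"price_per_mg"`, `"cost:<field>"`,
#'   `"ae_prob:<ae>"`, `"ae_cost:<ae>"`, `"ae_ur:<ae>"`, or the multipliers
#'   `"price_multiplier"` / `"progression_risk_multiplier"`.
#' @param values numeric grid.
#' @return A data frame of class `cea_sweep` with the grid value, the
#'   incremental cost/QALY/LY, the ICER and the dominance flag per row.
#' @export
sensitivity_one_way <- function(model, param, values) {
  rows <- lapply(values, function(v) {
    cmp <- rerun_with(model, param, v)$comparison
    data.frame(param = param, value = v, delta_cost = cmp$delta_cost,
               delta_qaly = cmp$delta_qaly, delta_ly = cmp$delta_ly,
               icer = cmp$icer_qaly, dominance = cmp$dominance)
  })
  structure(do.call(rbind, rows), class = c("cea_sweep", "data.frame"))
}

#' Two-way deterministic sensitivity analysis
#'
#' Full grid over two parameters; each grid point re-runs the pipeline.
#'
#' @param model a fitted `cea_model`.
#' @param param_a,param_b parameter ids (see [sensitivity_one_way()]).
#' @param values_a,values_b numeric grids.
#' @return A data frame of class `cea_sweep` with one row per grid point
#'   (`value_a`, `value_b`, increments, `icer`, `dominance`).
#' @export
sensitivity_two_way <- function(model, param_a, param_b, values_a, values_b) {
  grid <- expand.grid(value_a = values_a, value_b = values_b)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m1 <- rerun_with(model, param_a, grid$value_a[i])
    cmp <- rerun_with(m1, param_b, grid$value_b[i])$comparison
    data.frame(param_a = param_a, param_b = param_b,
               value_a = grid$value_a[i], value_b = grid$value_b[i],
               delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
               delta_ly = cmp$delta_ly, icer = cmp$icer_qaly,
               dominance = cmp$dominance)
  })
  structure(do.call(rbind, rows), class = c("cea_sweep", "data.frame"))
}

# ICER on the money-metric scale used for bracketing: dominant outcomes
# count as arbitrarily favourable.
icer_for_threshold <- function(cmp) {
  if (cmp$dominance == "dominant") return(-Inf)
  if (cmp$dominance == "dominated") return(Inf)
  cmp$icer_qaly
}

#' Threshold analysis by bisection
#'
#' Finds the fractional reduction of a parameter at which the ICER crosses
#' the willingness-to-pay threshold. A reduction `x` multiplies the
#' parameter by `1 - x`; `param = "price_reduction"` scales the cetuximab
#' unit price per mg, `param = "progression_risk_reduction"` scales the
#' arm-C monthly stable-to-progression probabilities. Bisection stops when
#' the ICER is within 0.1% of `wtp` or the bracket is narrower than 1e-4.
#'
#' @param model a fitted `cea_model`.
#' @param param `"price_reduction"` or `"progression_risk_reduction"`.
#' @param wtp willingness-to-pay threshold (CAD/QALY).
#' @param lo,hi bracketing reductions (defaults 0 and 1); the ICER at `lo`
#'   must be above `wtp` or 0 is returned (no reduction needed), and the
#'   ICER at `hi` must be below `wtp` or an error reports both endpoints.
#' @return the threshold reduction (fraction in `[lo, hi]`).
#' @export
threshold_search <- function(model,
                             param = c("price_reduction",
                                       "progression_risk_reduction"),
                             wtp = model$params$settings$wtp,
                             lo = 0, hi = 1) {
  param <- match.arg(param)
  mult_id <- switch(param,
                    price_reduction = "price_multiplier",
                    progression_risk_reduction = "progression_risk_multiplier")
  f <- function(x) icer_for_threshold(rerun_with(model, mult_id,
                                                 1 - x)$comparison)
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo <= wtp) return(lo)
  if (f_hi > wtp)
    stop("no threshold in bracket: ICER at reduction ", lo, " is ",
         round(f_lo), ", at ", hi, " is ", round(f_hi))
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (is.finite(f_mid) && abs(f_mid - wtp) <= 0.001 * wtp) return(mid)
    if (hi - lo < 1e-4) return(mid)
    if (f_mid > wtp) lo <- mid else hi <- mid
  }
}

#' Alternate-horizon analysis
#'
#' Re-runs the full pipeline at another time horizon (24 to 60 months).
#' Beyond the observed follow-up the transition probabilities continue at
#' the year-2 average, as in the base case.
#'
#' @param model a fitted `cea_model`.
#' @param horizon months.
#' @return The refitted `cea_model`.
#' @export
horizon_variant <- function(model, horizon) {
  if (horizon < 24)
    stop("horizon below 24 months is not supported (the observed follow-up)")
  cea_model(model$params, curves = NULL, horizon = horizon,
            price_multiplier = model$price_multiplier,
            progression_multiplier = model$progression_multiplier)
}
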