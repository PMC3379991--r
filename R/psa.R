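# Probabilistic sensitivity analysis: joint resampling of every declared
# Beta / lognormal parameter distribution, cost-effectiveness plane,
# acceptability curves and expected value of perfect information.

#' Draw from a distribution specification
#'
#' `beta_counts` draws from `Beta(alpha = n, beta = N - n)` (mean `n/N`);
#' `lognormal_mean_median` from the lognormal with `mu = log(median)` and
#' `sigma = sqrt(2 * log(mean/median))`, which has exactly the stated mean
#' and median; `fixed` returns the value. Degenerate specs (`n = N`, or
#' `mean = median`) return their point mass.
#'
#' @param spec a [dist_spec].
#' @param n number of draws (uses the current RNG stream).
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n = 1) {
  switch(spec$kind,
    fixed = rep(spec$p1, n),
    beta_counts = {
      if (spec$p1 == spec$p2) rep(1, n)
      else stats::rbeta(n, spec$p1, spec$p2 - spec$p1)
    },
    lognormal_mean_median = {
      if (spec$p1 == spec$p2) rep(spec$p1, n)
      else stats::rlnorm(n, meanlog = log(spec$p2),
                         sdlog = sqrt(2 * log(spec$p1 / spec$p2)))
    })
}

# The sampled-parameter plan: id -> (dist getter, setter).  Ids are stable
# names so each parameter owns its own random substream.
psa_plan <- function(params) {
  plan <- list()
  add <- function(id, spec, set) plan[[id]] <<- list(spec = spec, set = set)
  add("utility_stable", params$utilities$stable_dist,
      function(p, v) { p$utilities$stable <- v; p })
  add("utility_progression", params$utilities$progression_dist,
      function(p, v) {
        p$utilities$progression <- min(v, p$utilities$stable); p
      })
  for (f in c("chemo_monthly_total", "pharmacy_prep",
              "cetuximab_dose_month1", "cetuximab_dose_later",
              "infusion_month1", "infusion_later", "progression_monthly",
              "mild_ae_monthly_antihistamine", "mild_ae_monthly_skin")) {
    local({
      ff <- f
      add(paste0("cost:", ff), params$costs[[paste0(ff, "_dist")]],
          function(p, v) { p$costs[[ff]] <- v; p })
    })
  }
  for (ae in ae_names()) {
    local({
      a <- ae
      prof <- params$adverse_events[[a]]
      add(paste0("ae_prob:", a), prof$prob_dist,
          function(p, v) { p$adverse_events[[a]]$monthly_prob <- v; p })
      if (a != "mild") {
        add(paste0("ae_ur:", a), prof$ur_dist,
            function(p, v) { p$adverse_events[[a]]$utility_reduction <- v; p })
        add(paste0("ae_cost:", a), prof$cost_dist,
            function(p, v) { p$adverse_events[[a]]$management_cost <- v; p })
      }
    })
  }
  plan
}

# Deterministic per-parameter substream seed, derived from the master seed
# and the parameter id (not its position), so adding a parameter leaves the
# other parameters' draws unchanged.
substream_seed <- function(master, id) {
  bytes <- utf8ToInt(id)
  h <- sum(bytes * seq_along(bytes) * 131) %% 1e6
  as.integer((as.numeric(master) * 1e6 + h) %% .Machine$integer.max)
}

#' Draw the joint PSA parameter sample
#'
#' One independent substream per parameter id, seeded from the master seed
#' and the id.
#'
#' @param params base `cea_parameters`.
#' @param n replicates.
#' @param seed master seed.
#' @return matrix `n x parameters` of draws, with parameter ids as column
#'   names.
#' @export
sample_psa_parameters <- function(params, n, seed) {
  plan <- psa_plan(params)
  draws <- matrix(NA_real_, n, length(plan),
                  dimnames = list(NULL, names(plan)))
  for (id in names(plan)) {
    set.seed(substream_seed(seed, id))
    draws[, id] <- sample_distribution(plan[[id]]$spec, n)
  }
  draws
}

#' Run the probabilistic sensitivity analysis
#'
#' Jointly resamples every declared parameter distribution (adverse-event
#' probabilities, utilities and utility reductions, costs) and re-runs both
#' arms once per replicate. Survival and transition schedules are held at
#' their base-case calibration: the source tables declare distributions
#' only for probabilities, utilities and costs, and none for the
#' transition streams (a documented limitation). Deterministic given
#' `seed`.
#'
#' @param model a fitted `cea_model`.
#' @param n number of replicates (the headline analysis uses 10,000).
#' @param seed master seed.
#' @return An object of class `cea_psa`: `samples` (data frame with one
#'   row per replicate: per-arm discounted cost/QALY and the increments),
#'   the base-case comparison, `n`, `seed`.
#' @export
run_psa <- function(model, n, seed = 1L) {
  stopifnot(n >= 1)
  params <- model$params
  draws <- sample_psa_parameters(params, n, seed)
  plan <- psa_plan(params)

  sched_P <- model$schedules$P
  sched_C <- model$schedules$C
  space_P <- build_state_space("P")
  space_C <- build_state_space("C")
  trace_P <- model$traces$P  # arm P occupancy is unaffected by the draws

  out <- matrix(NA_real_, n, 8, dimnames = list(NULL, c(
    "cost_P", "qaly_P", "ly_P", "cost_C", "qaly_C", "ly_C",
    "delta_cost", "delta_qaly")))
  for (i in seq_len(n)) {
    p <- params
    for (id in colnames(draws)) p <- plan[[id]]$set(p, draws[i, id])
    res_P <- accumulate(trace_P, p, sched_P)
    trace_C <- run_cohort(space_C, sched_C, p)
    res_C <- accumulate(trace_C, p, sched_C)
    out[i, ] <- c(res_P$cost, res_P$qaly, res_P$ly,
                  res_C$cost, res_C$qaly, res_C$ly,
                  res_C$cost - res_P$cost, res_C$qaly - res_P$qaly)
  }
  samples <- data.frame(replicate = seq_len(n), out)
  structure(list(samples = samples, draws = draws, n = n, seed = seed,
                 base = model$comparison,
                 wtp = params$settings$wtp),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d replicates (seed %s)\n", x$n, format(x$seed)))
  cat(sprintf("  mean increment: cost $%s, %.4f QALY\n",
              format(round(mean(x$samples$delta_cost)), big.mark = ","),
              mean(x$samples$delta_qaly)))
  cat(sprintf("  P(cetuximab cost-effective at $%s/QALY) = %.3f\n",
              format(x$wtp, big.mark = ","),
              ceac(x, x$wtp)$prob_cetuximab))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA replicates in
#' which the cetuximab strategy has the higher net monetary benefit, i.e.
#' `wtp * delta_qaly - delta_cost > 0`; exact ties count one half. The
#' complementary probability belongs to the chemotherapy-alone strategy,
#' so the two curves sum to one at every point.
#'
#' @param psa a `cea_psa`.
#' @param wtp_grid willingness-to-pay values (CAD/QALY).
#' @return data frame with `wtp`, `prob_cetuximab`, `prob_chemo`.
#' @export
ceac <- function(psa, wtp_grid) {
  s <- psa$samples
  prob <- vapply(wtp_grid, function(w) {
    inmb <- w * s$delta_qaly - s$delta_cost
    mean((inmb > 0) + 0.5 * (inmb == 0))
  }, 0)
  data.frame(wtp = wtp_grid, prob_cetuximab = prob, prob_chemo = 1 - prob)
}

#' Expected value of perfect information
#'
#' Per-person EVPI at a willingness-to-pay threshold:
#' `E[max(NMB_C, NMB_P)] - max(E[NMB_C], E[NMB_P])`, computed on the
#' incremental scale as `mean(pmax(INMB, 0)) - max(mean(INMB), 0)` with
#' `INMB = wtp * delta_qaly - delta_cost`. Always non-negative; zero
#' exactly when one strategy is optimal in every replicate.
#'
#' @param psa a `cea_psa`.
#' @param wtp willingness-to-pay (CAD/QALY); may be a vector.
#' @return numeric EVPI (CAD per person), one value per `wtp`.
#' @export
evpi <- function(psa, wtp) {
  s <- psa$samples
  vapply(wtp, function(w) {
    inmb <- w * s$delta_qaly - s$delta_cost
    mean(pmax(inmb, 0)) - max(mean(inmb), 0)
  }, 0)
}

#' Plot method for PSA results
#'
#' `type = "scatter"` draws the incremental cost-effectiveness plane with
#' the willingness-to-pay line; `type = "ceac"` draws both strategies'
#' acceptability curves.
#'
#' @param x a `cea_psa`.
#' @param type `"scatter"` or `"ceac"`.
#' @param wtp_grid grid for the CEAC (default 0 to 500,000 by 10,000).
#' @param ... passed to the underlying plot call.
#' @export
plot.cea_psa <- function(x, type = c("scatter", "ceac"),
                         wtp_grid = seq(0, 5e5, 1e4), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    s <- x$samples
    graphics::plot(s$delta_qaly, s$delta_cost, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "incremental QALYs",
                   ylab = "incremental cost (CAD)", ...)
    graphics::abline(h = 0, v = 0, col = "grey70")
    graphics::abline(a = 0, b = x$wtp, col = "firebrick", lty = 2)
  } else {
    cc <- ceac(x, wtp_grid)
    graphics::matplot(cc$wtp, cbind(cc$prob_cetuximab, cc$prob_chemo),
                      type = "l", lty = 1, lwd = 2,
                      col = c("firebrick", "grey40"), ylim = c(0, 1),
                      xlab = "willingness to pay (CAD/QALY)",
                      ylab = "P(strategy cost-effective)", ...)
    graphics::legend("right", c("cetuximab + chemo", "chemo alone"),
                     col = c("firebrick", "grey40"), lwd = 2, bty = "n")
  }
  invisible(x)
}
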