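test_that("state utilities apply the multiplicative decrement", {
  p <- default_parameters()
  expect_equal(state_utility("progression", p), 0.52)
  expect_equal(state_utility("dead", p), 0)
  expect_equal(state_utility("stable", p), 0.65)
  expect_equal(state_utility("stable_mild_ae", p), 0.65)
  # severe skin within its 2-month decrement: 0.65 * (1 - 0.657)
  expect_equal(state_utility("stable_skin_severe", p, 1), 0.22295)
  expect_equal(state_utility("stable_skin_severe", p, 2), 0.65)
  # sepsis never reverts
  expect_equal(state_utility("stable_sepsis", p, 35), 0.65 * (1 - 0.41))
  expect_error(state_utility("stable_nonsense", p), "unknown state")
})

test_that("cetuximab dosing costs follow the dosing-rule footnotes", {
  co <- default_parameters()$costs
  m1 <- cetuximab_monthly_cost(1, co)
  ml <- cetuximab_monthly_cost(2, co)
  expect_equal(m1$drug, (400 + 3 * 250) * 1.8 * 3.24)   # 6706.8
  expect_equal(ml$drug, 4 * 250 * 1.8 * 3.24)           # 5832
  expect_equal(m1$infusion, 103.64 * 5)                 # 518.2
  expect_equal(ml$infusion, 103.64 * 4)                 # 414.56
  expect_equal(m1$prep, 160)
  expect_equal(m1$total, m1$drug + m1$infusion + 160)

  co0 <- co; co0$unit_price_per_mg <- 0
  z <- cetuximab_monthly_cost(1, co0)
  expect_equal(z$drug, 0)
  expect_equal(z$infusion, 518.2)  # chair time unaffected by drug price

  # explicit overrides (as sampled in PSA) take precedence
  co2 <- co; co2$cetuximab_dose_month1 <- 7000
  expect_equal(cetuximab_monthly_cost(1, co2)$drug, 7000)
  expect_equal(cetuximab_monthly_cost(2, co2)$drug, 5832)
})

test_that("trapezoidal accrual matches the hand example", {
  # alive 1, 0.5, 0.25; utility 1; no discounting ->
  # (1+0.5)/2 + (0.5+0.25)/2 = 1.125 occupancy-months
  p <- default_parameters()
  p$settings$annual_discount <- 0
  p$utilities$stable <- 1; p$utilities$progression <- 1
  sched <- make_schedule(0, 0.5, 0, n = 2)
  tr <- run_cohort(build_state_space("P"), sched, p)
  r <- accumulate(tr, p, sched)
  expect_equal(r$ly * 12, 1.125, tolerance = 1e-12)
  expect_equal(r$qaly * 12, 1.125, tolerance = 1e-12)
  expect_equal(r$cost, r$cost0)  # zero discount: twins coincide
})

test_that("monthly discounting matches an independent geometric sum", {
  p <- default_parameters()
  p$costs$progression_monthly <- 100
  sched <- make_schedule(0, 0, 0, n = 12)
  tr <- run_cohort(build_state_space("P"), sched, p,
                   initial = c(0, 1, 0))  # all mass parked in progression
  r <- accumulate(tr, p, sched)
  a <- 1.05^(-1 / 12)
  expect_equal(r$cost, 100 * a * (1 - a^12) / (1 - a), tolerance = 1e-12)
  expect_equal(r$cost0, 1200, tolerance = 1e-12)
})

test_that("cost streams respect the duration rules", {
  m <- base_model()
  comp_P <- cycle_costs(m$traces$P, m$params)
  # chemotherapy only in the first 5 calendar months
  expect_true(all(comp_P[1:5, "chemo"] > 0))
  expect_equal(sum(comp_P[6:36, "chemo"]), 0)
  expect_equal(sum(comp_P[, c("cetux_drug", "cetux_infusion", "cetux_prep",
                              "mild_ae", "severe_ae")]), 0)

  comp_C <- cycle_costs(m$traces$C, m$params)
  expect_true(all(comp_C[, "progression"] >= 0))
  # a unit entrant into sepsis at one cycle incurs exactly the case cost
  sep_ent <- m$traces$C$entrants[, "stable_sepsis"]
  manual <- sum(32462 * sep_ent) +
    sum(8436 * m$traces$C$entrants[, "stable_anorexia"]) +
    sum(5516 * m$traces$C$entrants[, "stable_hypomagnesemia"]) +
    sum(2912 * m$traces$C$entrants[, "stable_skin_severe"]) +
    sum(3764 * m$traces$C$entrants[, "stable_allergy_anaphylaxis"]) +
    sum(3991 * m$traces$C$entrants[, "stable_dyspnea"]) +
    sum(3234 * m$traces$C$entrants[, "stable_hypotension"])
  expect_equal(sum(comp_C[, "severe_ae"]), manual, tolerance = 1e-9)

  # a cohort that is entirely dead accrues nothing
  dead_tr <- run_cohort(build_state_space("P"),
                        make_schedule(0, 0, 0, n = 4), m$params,
                        initial = c(0, 0, 1))
  expect_equal(sum(cycle_costs(dead_tr, m$params)), 0)
})

test_that("setting every utility to one makes QALYs equal life-years", {
  p <- default_parameters()
  p$utilities$stable <- 1; p$utilities$progression <- 1
  for (ae in names(p$adverse_events))
    p$adverse_events[[ae]]$utility_reduction <- 0
  m <- cea_model(p)
  for (arm in c("P", "C"))
    expect_equal(m$results[[arm]]$qaly, m$results[[arm]]$ly,
                 tolerance = 1e-12)
})

test_that("QALYs never exceed utility-weighted life-years", {
  m <- base_model()
  for (arm in c("P", "C")) {
    r <- m$results[[arm]]
    expect_lte(r$qaly, r$ly * 0.65 + 1e-12)
    expect_lte(r$cost, r$cost0)
    expect_lte(r$qaly, r$qaly0)
  }
})

test_that("the incremental comparison forms ICERs and dominance flags", {
  res <- function(cost, qaly, ly) {
    structure(list(arm = "x", cost = cost, qaly = qaly, ly = ly,
                   cost0 = cost, qaly0 = qaly, ly0 = ly),
              class = "econ_result")
  }
  # the printed increments: 36,000 / 0.093 ~= 387,097 per QALY
  cmp <- compare(res(136000, 0.593, 1.0), res(100000, 0.5, 0.9))
  expect_equal(cmp$icer_qaly, 36000 / 0.093, tolerance = 1e-9)
  expect_equal(cmp$delta_ly, 0.1, tolerance = 1e-12)
  expect_equal(cmp$dominance, "none")

  expect_equal(compare(res(90000, 0.6, 1), res(100000, 0.5, 0.9))$dominance,
               "dominant")
  expect_equal(compare(res(110000, 0.4, 1), res(100000, 0.5, 0.9))$dominance,
               "dominated")
  same <- compare(res(1e5, 0.5, 1), res(1e5, 0.5, 1))
  expect_equal(same$dominance, "undefined")
  expect_true(is.na(same$icer_qaly))
})

test_that("arm C costs dominate arm P costs under nesting", {
  # identical schedules and no AEs: the only cost difference is cetuximab
  params <- no_ae_params()
  sched <- base_model()$schedules$P
  res <- lapply(c("P", "C"), function(arm)
    accumulate(run_cohort(build_state_space(arm), sched, params),
               params, sched))
  expect_gte(res[[2]]$cost, res[[1]]$cost)
  expect_equal(res[[2]]$qaly, res[[1]]$qaly, tolerance = 1e-12)
  # with cetuximab-related costs removed as well, the costs coincide
  params$costs$unit_price_per_mg <- 0
  params$costs$chair_rate <- 0
  params$costs$pharmacy_prep <- 0
  res0 <- lapply(c("P", "C"), function(arm)
    accumulate(run_cohort(build_state_space(arm), sched, params),
               params, sched))
  expect_equal(res0[[2]]$cost, res0[[1]]$cost, tolerance = 1e-9)
})
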