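test_that("state spaces enumerate the two models", {
  P <- build_state_space("P")
  C <- build_state_space("C")
  expect_length(P$states, 3)
  expect_equal(sum(P$absorbing), 1)
  expect_length(C$states, 11)
  expect_equal(sum(C$absorbing), 1)
  expect_equal(sum(C$on_cetuximab), 2)  # stable no-AE and mild-AE only
  # shared progression/dead semantics
  for (sp in list(P, C)) {
    expect_true("progression" %in% sp$states && "dead" %in% sp$states)
    expect_true(sp$absorbing[sp$states == "dead"])
  }
})

test_that("transition matrices are row-stochastic in both arms", {
  m <- base_model()
  for (arm in c("P", "C")) {
    sp <- build_state_space(arm)
    for (cyc in c(1, 2, 12, 36)) {
      M <- transition_matrix_at(sp, m$schedules[[arm]], m$params, cyc)
      expect_equal(rowSums(M), setNames(rep(1, length(sp$states)),
                                        sp$states), tolerance = 1e-12)
      expect_true(all(M >= 0))
    }
  }
})

test_that("first-month adverse events are closed off after cycle 1", {
  m <- base_model()
  sp <- build_state_space("C")
  M1 <- transition_matrix_at(sp, m$schedules$C, m$params, 1)
  M2 <- transition_matrix_at(sp, m$schedules$C, m$params, 2)
  first_month_states <- c("stable_mild_ae", "stable_allergy_anaphylaxis",
                          "stable_dyspnea", "stable_hypotension",
                          "stable_skin_severe")
  expect_true(all(M1["stable_no_ae", first_month_states] > 0))
  expect_equal(unname(M2["stable_no_ae", first_month_states]), rep(0, 5))
  # ongoing AEs remain open from both cetuximab-receiving states
  ongoing_states <- c("stable_anorexia", "stable_hypomagnesemia",
                      "stable_sepsis")
  expect_true(all(M2["stable_no_ae", ongoing_states] > 0))
  expect_true(all(M2["stable_mild_ae", ongoing_states] > 0))
  # severe-AE states admit no further AE moves
  expect_equal(unname(M2["stable_sepsis", c(first_month_states,
                                            setdiff(ongoing_states,
                                                    "stable_sepsis"))]),
               rep(0, 7))
})

test_that("cohort runs match hand-computed toy chains", {
  # 'survive or die' at 0.5/cycle: alive occupancies 1, 0.5, 0.25
  sched <- make_schedule(0, 0.5, 0, n = 2)
  tr <- run_cohort(build_state_space("P"), sched, default_parameters())
  expect_equal(unname(tr$occupancy[, "stable"]), c(1, 0.5, 0.25))

  # absorbing start: mass placed in dead stays there
  tr2 <- run_cohort(build_state_space("P"), sched, default_parameters(),
                    initial = c(0, 0, 1))
  expect_equal(unname(tr2$occupancy[, "dead"]), rep(1, 3))
  expect_equal(sum(tr2$occupancy[, c("stable", "progression")]), 0)
})

test_that("occupancy is conserved and death is monotone on random schedules", {
  set.seed(42)
  params <- default_parameters()
  for (rep in 1:8) {
    p_sp <- runif(36, 0, 0.5)
    p_sd <- runif(36, 0, 1 - max(p_sp)) * 0.5
    sched <- make_schedule(p_sp, p_sd, runif(36))
    for (arm in c("P", "C")) {
      tr <- run_cohort(build_state_space(arm), sched, params)
      expect_equal(unname(rowSums(tr$occupancy)), rep(1, 37),
                   tolerance = 1e-9)
      expect_true(all(tr$occupancy >= -1e-12))
      expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
    }
  }
})

test_that("with no adverse events model C nests model P exactly", {
  # same transition schedule for both state spaces: the nesting is a
  # property of the engine, not of the arm-specific survival inputs
  params <- no_ae_params()
  sched <- base_model()$schedules$P
  trP <- run_cohort(build_state_space("P"), sched, params)$occupancy
  trC <- run_cohort(build_state_space("C"), sched, params)$occupancy
  expect_equal(unname(trC[, "stable_no_ae"]), unname(trP[, "stable"]),
               tolerance = 1e-12)
  expect_equal(unname(trC[, "progression"]), unname(trP[, "progression"]),
               tolerance = 1e-12)
  expect_equal(unname(trC[, "dead"]), unname(trP[, "dead"]),
               tolerance = 1e-12)
  expect_equal(sum(trC[, setdiff(colnames(trC),
                                 c("stable_no_ae", "progression", "dead"))]),
               0)
})

test_that("the engine carries the survival calibration through to the trace", {
  m <- base_model()
  for (arm in c("P", "C")) {
    alive <- 1 - m$traces[[arm]]$occupancy[, "dead"]
    os <- m$curves[[paste0("os_", arm)]]$surv
    feasible <- setdiff(2:24, m$schedules[[arm]]$clipped)
    expect_equal(unname(alive[feasible + 1]), os[feasible + 1],
                 tolerance = 1e-9)
  }
})

test_that("entrants record inflows consistently with occupancy", {
  m <- base_model()
  tr <- m$traces$C
  r <- markovcea:::stable_retention(m$schedules$C, tr$horizon)
  for (st in c("stable_sepsis", "stable_skin_severe")) {
    occ <- tr$occupancy[, st]
    ent <- tr$entrants[, st]
    rebuilt <- numeric(length(occ)); rebuilt[1] <- 0
    for (t in seq_len(tr$horizon))
      rebuilt[t + 1] <- rebuilt[t] * r[t] + ent[t]
    expect_equal(rebuilt, unname(occ), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("traces export to tidy CSV", {
  m <- base_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(m$traces$P, path)
  d <- utils::read.csv(path)
  expect_equal(nrow(d), 3 * 37)
  expect_equal(sort(unique(d$state)), sort(build_state_space("P")$states))
})
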