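test_that("conditional event probabilities match hand computation", {
  expect_equal(conditional_event_probs(survival_curve(0:2, c(1, 0.8, 0.6))),
               c(0.2, 0.25))
  expect_equal(conditional_event_probs(survival_curve(0:5, rep(1, 6))),
               rep(0, 5))
  # exponential with median 7.4: constant monthly hazard 1 - 2^(-1/7.4)
  cu <- make_survival_curve(1, 7.4 / log(2), 24)
  expect_equal(conditional_event_probs(cu), rep(1 - 2^(-1 / 7.4), 24),
               tolerance = 1e-12)
})

test_that("other-cause splitting follows the multiplicative convention", {
  expect_equal(split_other_cause(c(0.1, 0.2), 0), c(0.1, 0.2))
  expect_equal(split_other_cause(0.10, 0.02), 1 - 0.90 / 0.98,
               tolerance = 1e-12)
  expect_equal(split_other_cause(0.01, 0.02), 0)  # floored
  expect_error(split_other_cause(0.5, 1), "degenerate")
})

test_that("progression mortality solves the two-cycle toy exactly", {
  pfs <- survival_curve(0:2, c(1, 0.5, 0.25))
  os <- survival_curve(0:2, c(1, 1.0, 0.75))
  cal <- calibrate_progression_mortality(os, pfs, 0)
  expect_equal(cal$p_prog_dead, c(0, 0.5), tolerance = 1e-12)
  expect_equal(cal$p_stable_prog, c(0.5, 0.5), tolerance = 1e-12)
  expect_length(cal$clipped, 0)
  expect_equal(max(abs(cal$residual)), 0, tolerance = 1e-12)
})

test_that("background equal to the whole OS decline leaves no excess deaths", {
  q <- 0.01
  os <- survival_curve(0:6, (1 - q)^(0:6))
  pfs <- survival_curve(0:6, (1 - q)^(0:6) * (1 - 0.2)^(0:6))
  cal <- calibrate_progression_mortality(os, pfs, q, warn = FALSE)
  # all OS decline beyond background must come from progression; here the
  # progression pool supplies it without any probability above the solver's
  # feasible range after cycle 1
  resim_alive <- local({
    s <- 1; g <- 0; out <- numeric(6)
    for (t in 1:6) {
      inflow <- s * cal$p_stable_prog[t]
      s <- s * (1 - cal$p_stable_prog[t]) * (1 - q)
      g <- (g + inflow) - g * cal$p_prog_dead[t]
      out[t] <- s + g
    }
    out
  })
  feasible <- setdiff(1:6, cal$clipped)
  expect_equal(resim_alive[feasible], os$surv[feasible + 1],
               tolerance = 1e-10)
})

test_that("re-simulating the fixture schedules reproduces the OS curves", {
  f <- make_fixture(horizon = 24)
  q <- f$life_table$monthly
  for (arm in c("P", "C")) {
    os <- f[[paste0("os_", arm)]]; pfs <- f[[paste0("pfs_", arm)]]
    cal <- calibrate_progression_mortality(os, pfs, q, warn = FALSE)
    feasible <- setdiff(seq_len(24), cal$clipped)
    expect_equal(max(abs(cal$residual[feasible])), 0, tolerance = 1e-9)
    # the only infeasible cycles are at the very start, before any
    # progression pool exists
    expect_true(all(cal$clipped <= 2))
    expect_true(all(cal$p_prog_dead >= 0 & cal$p_prog_dead <= 1))
    expect_true(all(cal$p_stable_prog + cal$p_stable_dead <= 1))
  }
})

test_that("calibration under zero background never exceeds the OS hazard", {
  f <- make_fixture(horizon = 24)
  os <- f$os_P
  cal <- calibrate_progression_mortality(os, os, 0, warn = FALSE)
  # with pfs = os every event is an OS event; probability mass conservation
  expect_true(all(cal$p_stable_prog <= conditional_event_probs(os) + 1e-12))
})

test_that("year-3 extrapolation uses the year-2 arithmetic mean", {
  s <- make_schedule(rep(0.05, 24), rep(0.001, 24),
                     rep(c(0.02, 0.04), 12))
  e <- extrapolate_year3(s, 36)
  expect_equal(e$p_stable_prog[25:36], rep(0.05, 12))
  expect_equal(e$p_prog_dead[25:36], rep(0.03, 12))  # mean of 0.02/0.04
  # the observed period is untouched, bit for bit
  expect_identical(e$p_stable_prog[1:24], s$p_stable_prog)
  expect_identical(e$p_prog_dead[1:24], s$p_prog_dead)
  expect_error(extrapolate_year3(make_schedule(rep(0.1, 12), 0, 0), 36),
               "at least 24")
})

test_that("schedules round-trip through tidy CSV", {
  m <- base_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(m$schedules$C, path)
  back <- read_schedule(path)
  for (f in c("p_stable_prog", "p_stable_dead", "p_prog_dead"))
    expect_equal(back[[f]], m$schedules$C[[f]], tolerance = 1e-12)
})

test_that("infeasible OS targets warn and saturate the probability", {
  # OS drops in month 1 although nobody has progressed yet
  os <- survival_curve(0:2, c(1, 0.9, 0.8))
  pfs <- survival_curve(0:2, c(1, 0.5, 0.25))
  expect_warning(calibrate_progression_mortality(os, pfs, 0),
                 "progression pool is empty")
})
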