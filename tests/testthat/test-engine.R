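test_that("discount weights follow the annual-step and continuous closed forms", {
  expect_equal(discount_weights(10, 0), rep(1, 10))
  w <- discount_weights(4, 0.035, 0.5, "annual_step")
  expect_equal(w, c(1, 1, 1 / 1.035, 1 / 1.035))
  wc <- discount_weights(3, 0.035, 0.5, "per_cycle_continuous")
  expect_equal(wc[3], 1.035^-1)
  expect_true(all(diff(discount_weights(74, 0.035)) <= 0))
  expect_error(discount_weights(10, -0.01), "nonnegative")
})

test_that("one cycle from the pure TAI state reproduces the transition row", {
  params <- nbd_parameters()
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  expect_equal(
    unname(trace$occupancy[2, ]),
    unname(transition_matrix(params, "TAI_PLUS_SBC")["TAI", ])
  )
  expect_identical(trace$n_cycles, 74L)
  expect_equal(unname(trace$occupancy[1, ]), c(1, 0, 0, 0))
})

test_that("identity dynamics leave occupancy constant and flows empty", {
  params <- params_with_matrix(list(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)
  ))
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  expect_true(all(trace$occupancy[, "TAI"] == 1))
  expect_equal(terminal_occupancy(trace, "STOMA"), 0)
  expect_true(all(state_entry_flows(trace, "STOMA")$inflow == 0))
})

test_that("a two-state toy chain decays geometrically", {
  params <- params_with_matrix(
    list(c(0.9, 0, 0, 0.1), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
    settings = list(horizon = 1.5)
  )
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  expect_equal(trace$occupancy[4, "TAI"], 0.9^3, ignore_attr = TRUE)
})

test_that("occupancy is conserved and stoma occupancy is nondecreasing", {
  set.seed(42)
  for (rep in 1:15) {
    params <- params_with_matrix(random_rows(), settings = list(horizon = 10))
    trace <- run_cohort(params, "TAI_PLUS_SBC")
    expect_equal(rowSums(trace$occupancy), rep(1, trace$n_cycles + 1),
      tolerance = 1e-9)
    expect_true(all(diff(trace$occupancy[, "STOMA"]) >= -1e-12))
    expect_true(all(trace$occupancy >= 0 & trace$occupancy <= 1 + 1e-12))
  }
})

test_that("the cohort engine agrees with a patient-level microsimulation", {
  rows <- list(
    c(0.90, 0.06, 0, 0.04), c(0, 0.85, 0, 0.15),
    c(0, 0, 1, 0), c(0, 0, 0, 1)
  )
  params <- params_with_matrix(rows, settings = list(
    horizon = 5, discount_rate_costs = 0, discount_rate_benefits = 0
  ))
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  m <- transition_matrix(params, "TAI_PLUS_SBC")
  sim <- simulate_patients(m, start = 1, n_cycles = 10, n_patients = 1e5, seed = 3)
  # occupancy within Monte-Carlo error (binomial SE < 0.0016)
  expect_lt(max(abs(sim - trace$occupancy)), 0.006)
  # expected event counts: analytic accrual vs occupancy-weighted recount
  fi_engine <- accrue_events(trace, params, "FI", discounted = FALSE)
  rate <- nbdcea:::per_cycle_event_rate(params, "FI")
  fi_sim <- sum(sim[1:10, ] %*% rate)
  expect_equal(fi_engine, fi_sim, tolerance = 0.01)
})

test_that("event accrual matches closed forms and discounting bounds", {
  # single non-absorbing state, no discounting: rate x horizon
  params <- params_with_matrix(
    list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
    settings = list(discount_rate_costs = 0, discount_rate_benefits = 0)
  )
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  expect_equal(accrue_events(trace, params, "UTI"), 0.67 * 37)

  # zero rates accrue nothing
  p0 <- nbd_parameters()
  p0$event_rates$rate <- 0
  trace0 <- run_cohort(p0, "SBC_ALONE")
  expect_equal(accrue_events(trace0, p0, "FI"), 0)

  # discounted accrual never exceeds undiscounted; equal when rate is 0
  pp <- nbd_parameters()
  tr <- run_cohort(pp, "SBC_ALONE")
  for (ev in c("FI", "UTI", "HOSP")) {
    expect_lt(
      accrue_events(tr, pp, ev, discounted = TRUE),
      accrue_events(tr, pp, ev, discounted = FALSE)
    )
  }
  expect_error(accrue_events(tr, pp, "FLU"), "arg")
})

test_that("entry flows conserve mass into the absorbing state", {
  params <- nbd_parameters()
  for (arm in nbd_arms()) {
    trace <- run_cohort(params, arm)
    flows <- state_entry_flows(trace, "STOMA")
    expect_equal(
      sum(flows$inflow),
      unname(terminal_occupancy(trace, "STOMA") - trace$occupancy[1, "STOMA"]),
      tolerance = 1e-12
    )
  }
  # one cycle from pure TAI: stoma inflow equals the resolved matrix entry
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  m <- transition_matrix(params, "TAI_PLUS_SBC")
  expect_equal(state_entry_flows(trace, "STOMA")$inflow[1], m["TAI", "STOMA"],
    ignore_attr = TRUE)
})

test_that("the engine refuses to run an invalid matrix", {
  params <- nbd_parameters()
  params$transitions$p[1] <- 0.5 # breaks the TAI row sum
  params$settings$row_sum_tolerance <- 1 # slip past load-time validation
  params$settings$row_deficit_policy <- "none"
  expect_error(run_cohort(params, "TAI_PLUS_SBC"), "invalid matrix")
})

test_that("tidy trace table is long, complete and carries weights", {
  trace <- run_cohort(nbd_parameters(), "SBC_ALONE")
  td <- tidy(trace)
  expect_identical(nrow(td), 75L * 4L)
  expect_true(all(is.na(td$weight_costs[td$cycle == 74])))
  expect_equal(td$weight_benefits[td$cycle == 0], rep(1, 4))
})
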