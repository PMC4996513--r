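test_that("per-cycle item costs follow pack arithmetic and frequency units", {
  items <- nbd_parameters()$cost_items
  movicol <- items[items$item == "movicol", ]
  expect_equal(per_cycle_item_cost(movicol), (11.13 / 50) * 365.25 / 2)
  catheters <- items[items$item == "tai_catheters", ]
  expect_equal(per_cycle_item_cost(catheters), 130.33 * 6)
  supp <- items[items$item == "supp_glycerine", ]
  expect_equal(per_cycle_item_cost(supp), (1.94 / 12) * 365.25 / 4)
  zero <- movicol
  zero$quantity <- 0
  expect_equal(per_cycle_item_cost(zero), 0)
  bad <- movicol
  bad$unit <- "fortnight"
  expect_error(per_cycle_item_cost(bad), "fortnight")
  expect_error(per_cycle_item_cost(items[items$item == "uti_treatment", ]),
    "per_event")
})

test_that("QALY accrual matches closed forms", {
  # single state, utility u, zero discount, no events: u x horizon
  params <- params_with_matrix(
    list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
    settings = list(discount_rate_costs = 0, discount_rate_benefits = 0)
  )
  params$event_rates$rate <- 0
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  expect_equal(accrue_qalys(trace, params), 0.565 * 37)

  params$utilities$utility <- 0
  expect_equal(accrue_qalys(trace, params), 0)

  # bounded above by max utility x discounted life years
  pp <- nbd_parameters()
  tr <- run_cohort(pp, "TAI_PLUS_SBC")
  ly <- sum(tr$weights_benefits) * 0.5
  expect_lt(accrue_qalys(tr, pp), max(pp$utilities$utility) * ly)
})

test_that("cost accrual is additive, linear, and handles one-off entries", {
  params <- nbd_parameters()
  trace <- run_cohort(params, "SBC_ALONE")
  res <- accrue_costs(trace, params)
  expect_equal(sum(res$breakdown$cost), res$total, tolerance = 1e-9)
  expect_true(all(res$breakdown$cost >= 0))

  # empty schedule
  p0 <- params
  p0$cost_items <- params$cost_items[0, ]
  expect_equal(accrue_costs(trace, p0)$total, 0)

  # doubling every pack cost exactly doubles the total
  p2 <- params
  p2$cost_items$pack_cost <- 2 * p2$cost_items$pack_cost
  expect_equal(accrue_costs(trace, p2)$total, 2 * res$total)

  # one-off cost C on the absorbing state, zero discount: C x terminal occupancy
  pz <- nbd_parameters(settings = list(
    discount_rate_costs = 0, discount_rate_benefits = 0
  ))
  pz$cost_items <- pz$cost_items[pz$cost_items$item == "stoma_surgery", ]
  tz <- run_cohort(pz, "SBC_ALONE")
  expect_equal(
    accrue_costs(tz, pz)$total,
    7459.76 * terminal_occupancy(tz, "STOMA")
  )
})

test_that("a hand-computed schedule reproduces the single-state cost total", {
  # cohort pinned in the TAI state, no discounting: every TAI-attached item
  # accrues for 74 cycles, entry items once
  params <- params_with_matrix(
    list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
    settings = list(discount_rate_costs = 0, discount_rate_benefits = 0)
  )
  trace <- run_cohort(params, "TAI_PLUS_SBC")
  total <- accrue_costs(trace, params)$total
  dpc <- 365.25 / 2
  recurring <- (44.89 / 20) * dpc + (5.95 / 7) * dpc + # plug + pad
    74.78 + 130.33 * 6 + # system + catheters
    142 * 0.88 / 2 + 37 * 0.19 / 2 + 234 * 2.89 / 2 + # HCP visits
    24 * (19 / 60) * dpc * 0.25 # caregiver
  events <- (1.5 * 365.25 / 7 / 2) * 74 # FI episodes over the horizon
  uti <- 0.67 / 2 * 74
  hosp <- 0.28 / 2 * 74
  oracle <- recurring * 74 + 142 + 300 + # entry consultation + 3 calls
    (44.89 / 20 + 5.95 / 7) * events + # pads and plugs per episode
    167.77 * uti +
    mean(c(1998.84, 2326.32, 1432.09)) * hosp
  expect_equal(total, oracle, tolerance = 1e-9)
})

test_that("incremental analysis classifies dominance correctly", {
  mk <- function(cost, qaly) {
    tibble::tibble(
      arm = "x", total_cost = cost, total_qalys = qaly, fi_episodes = 0,
      uti_episodes = 0, hospitalizations = 0, stoma_probability = 0
    )
  }
  same <- incremental_analysis(mk(100, 5), mk(100, 5))
  expect_equal(same$delta_cost, 0)
  expect_identical(same$icer_label, "equivalent")

  dom <- incremental_analysis(mk(148951, 11.6), mk(170719, 11.2))
  expect_identical(dom$icer_label, "DOMINANT")
  expect_true(is.na(dom$icer))

  quo <- incremental_analysis(mk(130000, 6), mk(100000, 5))
  expect_identical(quo$icer_label, "quotient")
  expect_equal(quo$icer, 30000)

  ud <- incremental_analysis(mk(120, 5), mk(100, 5))
  expect_identical(ud$icer_label, "undefined")
  expect_true(is.na(ud$icer))

  dominated <- incremental_analysis(mk(120, 4), mk(100, 5))
  expect_identical(dominated$icer_label, "DOMINATED")
})

test_that("base-case bundle is internally consistent", {
  fit <- run_base_case(nbd_parameters())
  # per-arm breakdowns sum to the reported totals
  for (arm in nbd_arms()) {
    expect_equal(
      sum(fit$breakdowns[[arm]]$cost),
      fit$arms$total_cost[fit$arms$arm == arm],
      tolerance = 1e-6
    )
  }
  # percentage changes recompute from the per-arm report
  tai <- fit$arms[fit$arms$arm == "TAI_PLUS_SBC", ]
  sbc <- fit$arms[fit$arms$arm == "SBC_ALONE", ]
  expect_equal(
    fit$pct_change$stoma_probability,
    -(1 - tai$stoma_probability / sbc$stoma_probability)
  )
  expect_equal(
    fit$pct_change$fi_episodes,
    (tai$fi_episodes - sbc$fi_episodes) / sbc$fi_episodes
  )
  # tidy/glance views agree with the underlying tables
  td <- tidy(fit)
  expect_equal(
    td$value[td$arm == "incremental" & td$outcome == "total_cost"],
    fit$incremental$delta_cost
  )
  gl <- glance(fit)
  expect_identical(gl$icer_label, "DOMINANT")
  expect_equal(gl$fi_reduction, -fit$pct_change$fi_episodes)
})
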