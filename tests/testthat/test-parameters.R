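test_that("default parameter set carries the published transition probabilities", {
  params <- nbd_parameters()
  tai_row <- params$transitions |>
    dplyr::filter(arm == "TAI_PLUS_SBC", from == "TAI") |>
    dplyr::arrange(match(to, nbd_states()))
  expect_equal(tai_row$p, c(0.9810, 0.0069, 0.0065, 0.0057))
  # SBC-alone arm has no TAI row
  expect_false("TAI" %in% params$transitions$from[params$transitions$arm == "SBC_ALONE"])
})

test_that("row-deficit policies resolve short rows as documented", {
  params <- nbd_parameters()
  # default: deficit of the surgical row joins the calibrated stoma column
  m <- transition_matrix(params, "SBC_ALONE")
  expect_equal(unname(m["SURGICAL", ]), c(0, 0, 0.9831, 0.0169))
  expect_equal(unname(rowSums(m)), rep(1, 4))
  # proportional renormalization divides the printed row by its sum
  m2 <- transition_matrix(params, "SBC_ALONE", policy = "renormalize")
  expect_equal(
    unname(m2["SURGICAL", c("SURGICAL", "STOMA")]),
    c(0.9831, 0.0116) / 0.9947
  )
  expect_equal(unname(rowSums(m2)), rep(1, 4))
  # the unreachable TAI row is the identity row in the comparator arm
  expect_equal(unname(m["TAI", ]), c(1, 0, 0, 0))
})

test_that("validate_matrix reports range and row-sum violations by row", {
  good <- transition_matrix(nbd_parameters(), "TAI_PLUS_SBC")
  expect_identical(nrow(validate_matrix(good)), 0L)

  bad_sum <- good
  bad_sum["RESUME_SBC", "SURGICAL"] <- bad_sum["RESUME_SBC", "SURGICAL"] + 0.2
  v <- validate_matrix(bad_sum)
  expect_identical(v$rule, "row_sums_to_one")
  expect_identical(v$row, "RESUME_SBC")

  bad_neg <- good
  bad_neg["TAI", "STOMA"] <- -0.01
  bad_neg["TAI", "TAI"] <- bad_neg["TAI", "TAI"] + 0.01 + 0.0056
  v <- validate_matrix(bad_neg)
  expect_true("entry_in_unit_interval" %in% v$rule)

  broken_absorbing <- good
  broken_absorbing["STOMA", ] <- c(0.01, 0, 0, 0.99)
  v <- validate_matrix(broken_absorbing)
  expect_true("absorbing_row_is_identity" %in% v$rule)
})

test_that("configuration files round-trip exactly", {
  params <- nbd_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(params, path)
  reloaded <- read_model_config(path)
  expect_equal(unclass(reloaded), unclass(params), tolerance = 1e-12)
})

test_that("the shipped canonical configuration equals the in-code defaults", {
  shipped <- read_model_config(default_config_path())
  expect_equal(unclass(shipped), unclass(nbd_parameters()), tolerance = 1e-12)
})

test_that("configuration errors name the offending key or row", {
  params <- nbd_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(params, path)
  cfg <- yaml::read_yaml(path)
  cfg$utilities <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path2)
  expect_error(read_model_config(path2), "utilities")

  bad <- params$transitions
  bad$p[bad$arm == "TAI_PLUS_SBC" & bad$from == "TAI" & bad$to == "STOMA"] <- 0.1
  expect_error(nbd_parameters(transitions = bad), "TAI")
  expect_error(read_model_config(withr::local_tempfile()), "not found|schema")
})

test_that("every published numeric input appears in the loaded parameter set", {
  params <- nbd_parameters()
  # transition probabilities
  expect_true(all(
    c(0.9810, 0.0069, 0.0065, 0.0057, 0.9692, 0.0113, 0.0195, 0.9891, 0.0109,
      0.9736, 0.0097, 0.0167, 0.9831, 0.0116) %in% params$transitions$p
  ))
  # utilities and decrements
  expect_setequal(params$utilities$utility, c(0.565, 0.548, 0.548, 0.505))
  expect_setequal(params$decrements$decrement, c(-0.060, -0.100))
  # event frequencies
  expect_setequal(params$event_rates$rate, c(1.5, 3.5, 0.67, 1.37, 0.28, 1.37))
  # unit costs
  expect_true(all(
    c(2.29, 6.98, 3.43, 11.13, 1.94, 1.57, 0.66, 44.89, 5.95, 74.78, 130.33,
      142.00, 100.00, 9368.00, 7770.00, 3870.33, 6286.00, 118.92, 7459.76,
      87.00, 6.78, 22.24, 14.96, 142.00, 37.00, 234.00, 24.00, 167.77,
      1998.84, 24214.00, 2326.32, 1432.09, 34.89, 3355.69) %in%
      params$cost_items$pack_cost
  ))
  # pack sizes and usage frequencies
  expect_true(all(c(30, 100, 50, 12, 20, 7) %in% params$cost_items$pack_size))
  expect_true(all(
    c(0.88, 1.04, 0.19, 0.57, 2.89, 3.75, 0.61, 0.18, 19 / 60, 26 / 60) %in%
      params$cost_items$quantity
  ))
  expect_true(all(c(0.25, 0.45) %in% params$cost_items$proportion))
})

test_that("parameter_table and set_parameter are mutually consistent", {
  params <- nbd_parameters()
  ptab <- parameter_table(params)
  expect_true(all(c("probability", "utility", "decrement", "rate", "cost",
    "proportion") %in% ptab$class))
  # list prices are excluded from sampling, other costs are not
  expect_false(ptab$sampled[ptab$parameter == "cost.movicol"])
  expect_true(ptab$sampled[ptab$parameter == "cost.stoma_surgery"])

  # writing a value back lands in the right slot
  p2 <- set_parameter(params, "utility.STOMA", 0.6)
  expect_equal(p2$utilities$utility[p2$utilities$state == "STOMA"], 0.6)
  p3 <- set_parameter(params, "cost.movicol", 20)
  expect_equal(p3$cost_items$pack_cost[p3$cost_items$item == "movicol"], 20)

  # perturbing a transition keeps the row on the simplex
  p4 <- set_parameter(params, "p.TAI_PLUS_SBC.RESUME_SBC.STOMA", 0.4)
  row <- p4$transitions |>
    dplyr::filter(arm == "TAI_PLUS_SBC", from == "RESUME_SBC")
  expect_equal(sum(row$p), 1)
  expect_gt(row$p[row$to == "STOMA"], 0.28)
  expect_error(set_parameter(params, "cost.not_an_item", 1), "unknown")
})

test_that("zero discount rates yield unit discount weights throughout", {
  params <- nbd_parameters(settings = list(
    discount_rate_costs = 0, discount_rate_benefits = 0
  ))
  trace <- run_cohort(params, "SBC_ALONE")
  expect_equal(trace$weights_costs, rep(1, 74))
  expect_equal(trace$weights_benefits, rep(1, 74))
})
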