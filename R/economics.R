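# Economics: discounted QALY accrual, itemised cost accrual, and
# incremental cost-effectiveness results.

# Uses of an item per model cycle for a unit period.
uses_per_cycle <- function(unit, quantity, cycle_length) {
  per_year <- c(
    day = DAYS_PER_YEAR, week = WEEKS_PER_YEAR, month = 12,
    four_months = 3, year = 1
  )
  if (unit %in% names(per_year)) {
    quantity * per_year[[unit]] * cycle_length
  } else if (unit == "cycle") {
    quantity
  } else {
    stop("unrecognised frequency unit: ", unit, call. = FALSE)
  }
}

#' Per-cycle cost of a recurring cost item
#'
#' Converts one row of the cost schedule into pounds per fully-occupied
#' cohort fraction per model cycle: unit cost (`pack_cost / pack_size`)
#' times the uses per cycle implied by the frequency (daily use is 182.625
#' uses per six-month cycle, alternate-day 91.3125, monthly 6, annual rate
#' `r` contributes `r / 2`, and so on) times the proportion of occupants
#' the item applies to.
#'
#' @param item One-row data frame (or list) with the cost-schedule columns.
#' @param settings Economic settings (for the cycle length).
#' @return GBP per occupied cohort fraction per cycle.
#' @examples
#' movicol <- dplyr::filter(nbd_parameters()$cost_items, item == "movicol")
#' per_cycle_item_cost(movicol) # (11.13 / 50) * 182.625
#' @export
per_cycle_item_cost <- function(item, settings = default_settings()) {
  if (!item$attachment %in% "state_recurring") {
    stop("per-cycle cost is defined for state_recurring items; '", item$item,
      "' is attached as ", item$attachment, call. = FALSE)
  }
  unit_cost <- item$pack_cost / item$pack_size
  unit_cost * uses_per_cycle(item$unit, item$quantity, settings$cycle_length) *
    item$proportion
}

# Discounted lifetime event counts for all three event types, at both
# discount bases (benefits for QALY decrements, costs for per-event costs).
discounted_event_counts <- function(trace, params) {
  events <- c("FI", "UTI", "HOSP")
  list(
    benefits = stats::setNames(
      vapply(events, function(e) accrue_events(trace, params, e, weights = "benefits"), 0), events),
    costs = stats::setNames(
      vapply(events, function(e) accrue_events(trace, params, e, weights = "costs"), 0), events)
  )
}

#' Discounted quality-adjusted life years of a cohort trace
#'
#' State occupancy times the state utility times the cycle length in years,
#' discounted at the benefits rate, minus per-event utility decrements.
#' Decrements are utility losses sustained for the duration of the episode
#' (`episode_days`), applied once per (discounted) event.
#'
#' @param trace An `nbd_trace`.
#' @param params The parameter set used to run the trace.
#' @param event_counts Optional named vector of discounted lifetime event
#'   counts; computed from the trace when omitted.
#' @return Discounted QALYs (scalar).
#' @export
accrue_qalys <- function(trace, params, event_counts = NULL) {
  s <- trace$settings
  u <- stats::setNames(params$utilities$utility, params$utilities$state)
  occ <- discounted_occupancy(trace, "benefits")
  base <- sum(occ * u[names(occ)]) * s$cycle_length
  if (is.null(event_counts)) {
    event_counts <- discounted_event_counts(trace, params)$benefits
  }
  dec <- params$decrements
  loss <- sum(
    -dec$decrement * (dec$episode_days / DAYS_PER_YEAR) *
      event_counts[dec$event],
    na.rm = TRUE
  )
  base - loss
}

#' Discounted lifetime costs of a cohort trace, itemised
#'
#' Accrues every item of the cost schedule over the trace: recurring items
#' per cycle of state occupancy, one-off items on the flows entering their
#' state (and on initial occupancy for the arm's start state), and
#' per-event items on discounted lifetime event counts. All costs are
#' discounted at the costs rate.
#'
#' @inheritParams accrue_qalys
#' @return A list with `total` (GBP) and `breakdown` (tibble `item`,
#'   `group`, `cost`, summing to the total).
#' @export
accrue_costs <- function(trace, params, event_counts = NULL) {
  s <- trace$settings
  items <- params$cost_items
  if (is.null(event_counts)) {
    event_counts <- discounted_event_counts(trace, params)$costs
  }
  occ_d <- discounted_occupancy(trace, "costs")
  entry_d <- vapply(nbd_states(), function(st) {
    fl <- state_entry_flows(trace, st, include_start = st == trace$start_state)
    sum(fl$inflow * trace$weights_costs)
  }, 0)
  bad_att <- setdiff(items$attachment, c("state_recurring", "state_entry", "per_event"))
  if (length(bad_att) > 0) {
    stop("unknown cost attachment: ", bad_att[1], call. = FALSE)
  }
  bad_ev <- setdiff(items$target[items$attachment == "per_event"], names(event_counts))
  if (length(bad_ev) > 0) {
    stop("cost item attached to unknown event type: ", bad_ev[1], call. = FALSE)
  }
  per_year <- c(
    day = DAYS_PER_YEAR, week = WEEKS_PER_YEAR, month = 12,
    four_months = 3, year = 1, cycle = 1 / s$cycle_length,
    one_off = 0, event = 0
  )
  bad_unit <- setdiff(items$unit, names(per_year))
  if (length(bad_unit) > 0) {
    stop("unrecognised frequency unit: ", bad_unit[1], call. = FALSE)
  }
  unit_cost <- items$pack_cost / items$pack_size
  base <- unit_cost * items$quantity * items$proportion
  cost <- numeric(nrow(items))
  rec <- items$attachment == "state_recurring"
  ent <- items$attachment == "state_entry"
  evt <- items$attachment == "per_event"
  cost[rec] <- base[rec] * per_year[items$unit[rec]] * s$cycle_length *
    occ_d[items$target[rec]]
  cost[ent] <- base[ent] * entry_d[items$target[ent]]
  cost[evt] <- base[evt] * unlist(event_counts)[items$target[evt]]
  breakdown <- tibble::tibble(item = items$item, group = items$group, cost = cost)
  list(total = sum(cost), breakdown = breakdown)
}

#' Lifetime discounted results of one treatment arm
#'
#' Runs the cohort model for one arm and accrues all outcomes: discounted
#' total cost (with per-item breakdown), discounted QALYs, expected lifetime
#' counts of fecal-incontinence episodes, treated UTIs and hospitalizations,
#' and the undiscounted probability of stoma surgery within the horizon.
#'
#' @param params An `nbd_parameters` object.
#' @param arm Arm name.
#' @return An object of class `nbd_arm_result`: a list with `summary`
#'   (one-row tibble) and `breakdown` (itemised costs).
#' @examples
#' run_arm(nbd_parameters(), "SBC_ALONE")$summary
#' @export
run_arm <- function(params, arm) {
  arm <- match.arg(arm, nbd_arms())
  trace <- run_cohort(params, arm)
  ev <- discounted_event_counts(trace, params)
  costs <- accrue_costs(trace, params, ev$costs)
  qalys <- accrue_qalys(trace, params, ev$benefits)
  structure(list(
    summary = tibble::tibble(
      arm = arm,
      total_cost = costs$total,
      total_qalys = qalys,
      fi_episodes = ev$benefits[["FI"]],
      uti_episodes = ev$benefits[["UTI"]],
      hospitalizations = ev$benefits[["HOSP"]],
      stoma_probability = terminal_occupancy(trace, "STOMA")
    ),
    breakdown = costs$breakdown,
    trace = trace
  ), class = "nbd_arm_result")
}

#' @export
print.nbd_arm_result <- function(x, ...) {
  cat("<nbd_arm_result>\n")
  print(x$summary)
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Differences every outcome of the intervention arm against the comparator
#' and classifies the incremental cost-effectiveness ratio: `DOMINANT` when
#' the intervention is cheaper and more effective, `DOMINATED` when costlier
#' and less effective, the cost-per-QALY quotient otherwise, and `undefined`
#' when the QALY difference is zero with a nonzero cost difference.
#'
#' @param intervention,comparator `nbd_arm_result` objects (or their
#'   one-row `summary` tibbles) computed under identical settings.
#' @return A one-row tibble with `delta_cost`, `delta_qalys`,
#'   `delta_fi_episodes`, `delta_uti_episodes`, `delta_hospitalizations`,
#'   `delta_stoma_probability`, `icer` (numeric; `NA` when labelled) and
#'   `icer_label`.
#' @export
incremental_analysis <- function(intervention, comparator) {
  a <- if (inherits(intervention, "nbd_arm_result")) intervention$summary else intervention
  b <- if (inherits(comparator, "nbd_arm_result")) comparator$summary else comparator
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qalys - b$total_qalys
  label <- if (dc < 0 && dq > 0) {
    "DOMINANT"
  } else if (dc > 0 && dq < 0) {
    "DOMINATED"
  } else if (dq == 0 && dc != 0) {
    "undefined"
  } else if (dq == 0 && dc == 0) {
    "equivalent"
  } else {
    "quotient"
  }
  tibble::tibble(
    delta_cost = dc,
    delta_qalys = dq,
    delta_fi_episodes = a$fi_episodes - b$fi_episodes,
    delta_uti_episodes = a$uti_episodes - b$uti_episodes,
    delta_hospitalizations = a$hospitalizations - b$hospitalizations,
    delta_stoma_probability = a$stoma_probability - b$stoma_probability,
    icer = if (label == "quotient") dc / dq else NA_real_,
    icer_label = label
  )
}

#' Run the full base-case cost-utility analysis
#'
#' Evaluates both treatment arms over the lifetime horizon and assembles
#' the cost-effectiveness summary: per-arm totals, incremental differences,
#' relative changes (incremental divided by the comparator value) and the
#' dominance classification.
#'
#' @param params An `nbd_parameters` object; defaults to the canonical
#'   published inputs.
#' @return An object of class `nbd_cea`: list with `arms` (two-row tibble),
#'   `incremental` (one-row tibble), `pct_change` (one-row tibble),
#'   `breakdowns` (per-arm itemised costs). `tidy()` returns the summary
#'   table in long form, `glance()` the headline one-row summary.
#' @examples
#' fit <- run_base_case(nbd_parameters())
#' glance(fit)
#' @export
run_base_case <- function(params = nbd_parameters()) {
  tai <- run_arm(params, "TAI_PLUS_SBC")
  sbc <- run_arm(params, "SBC_ALONE")
  inc <- incremental_analysis(tai, sbc)
  comp <- sbc$summary
  pct <- tibble::tibble(
    cost = inc$delta_cost / comp$total_cost,
    qalys = inc$delta_qalys / comp$total_qalys,
    fi_episodes = inc$delta_fi_episodes / comp$fi_episodes,
    uti_episodes = inc$delta_uti_episodes / comp$uti_episodes,
    hospitalizations = inc$delta_hospitalizations / comp$hospitalizations,
    stoma_probability = inc$delta_stoma_probability / comp$stoma_probability
  )
  structure(list(
    arms = dplyr::bind_rows(tai$summary, sbc$summary),
    incremental = inc,
    pct_change = pct,
    breakdowns = list(TAI_PLUS_SBC = tai$breakdown, SBC_ALONE = sbc$breakdown),
    params = params
  ), class = "nbd_cea")
}

#' @export
print.nbd_cea <- function(x, ...) {
  cat("<nbd_cea> lifetime cost-utility, TAI + SBC vs SBC alone\n\n")
  print(x$arms)
  cat(sprintf(
    "\nIncremental: cost %s%.0f GBP, QALYs %+.3f, ICER %s\n",
    ifelse(x$incremental$delta_cost < 0, "-", "+"),
    abs(x$incremental$delta_cost), x$incremental$delta_qalys,
    ifelse(is.na(x$incremental$icer), x$incremental$icer_label,
      sprintf("%.0f GBP/QALY", x$incremental$icer))
  ))
  invisible(x)
}

#' @export
#' @method tidy nbd_cea
tidy.nbd_cea <- function(x, ...) {
  arms_long <- x$arms |>
    tidyr::pivot_longer(-"arm", names_to = "outcome", values_to = "value")
  inc <- tibble::tibble(
    arm = "incremental",
    outcome = c("total_cost", "total_qalys", "fi_episodes", "uti_episodes",
      "hospitalizations", "stoma_probability"),
    value = c(x$incremental$delta_cost, x$incremental$delta_qalys,
      x$incremental$delta_fi_episodes, x$incremental$delta_uti_episodes,
      x$incremental$delta_hospitalizations, x$incremental$delta_stoma_probability)
  )
  pct <- tibble::tibble(
    arm = "pct_change",
    outcome = inc$outcome,
    value = c(x$pct_change$cost, x$pct_change$qalys, x$pct_change$fi_episodes,
      x$pct_change$uti_episodes, x$pct_change$hospitalizations,
      x$pct_change$stoma_probability)
  )
  dplyr::bind_rows(arms_long, inc, pct)
}

#' @export
#' @method glance nbd_cea
glance.nbd_cea <- function(x, ...) {
  dplyr::bind_cols(
    x$incremental[, c("delta_cost", "delta_qalys", "icer_label")],
    tibble::tibble(
      fi_reduction = -x$pct_change$fi_episodes,
      uti_reduction = -x$pct_change$uti_episodes,
      stoma_reduction = -x$pct_change$stoma_probability
    )
  )
}
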