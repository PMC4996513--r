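# Cohort engine: occupancy propagation, discount weights, event accrual.

#' Discount weights per model cycle
#'
#' `annual_step` mode reproduces spreadsheet-style annual discounting: the
#' weight changes once per model year, so both six-month cycles of year `y`
#' carry `(1 + rate)^-y`. `per_cycle_continuous` compounds smoothly at every
#' cycle.
#'
#' @param n_cycles Number of cycles.
#' @param rate Annual discount rate (fraction, `>= 0`).
#' @param cycle_length Cycle length in years.
#' @param mode `"annual_step"` or `"per_cycle_continuous"`.
#' @return Numeric vector of length `n_cycles` for cycles `0, 1, ...,
#'   n_cycles - 1`, each in `(0, 1]`, nonincreasing.
#' @examples
#' discount_weights(4, 0.035, 0.5) # first model year undiscounted
#' @export
discount_weights <- function(n_cycles, rate, cycle_length = 0.5,
                             mode = c("annual_step", "per_cycle_continuous")) {
  mode <- match.arg(mode)
  if (rate < 0) stop("discount rate must be nonnegative", call. = FALSE)
  t <- (seq_len(n_cycles) - 1) * cycle_length
  if (mode == "annual_step") t <- floor(t)
  (1 + rate)^(-t)
}

#' Propagate a cohort through the Markov model
#'
#' Runs the cohort trace for one treatment arm: the cohort starts entirely
#' in the arm's entry state and is propagated by the per-cycle transition
#' matrix over the full time horizon (74 six-month cycles in the base
#' case). No in-model mortality is applied; the fixed horizon — the life
#' expectancy shared by both arms — is the sole survival mechanism, so
#' occupancy is conserved at every cycle.
#'
#' @param params An `nbd_parameters` object.
#' @param arm Arm name.
#' @param start_state Entry state; defaults to [arm_start_state()].
#' @return An object of class `nbd_trace`: list with `occupancy` (matrix,
#'   `(n_cycles + 1) x 4`, rows are cycles `0..n_cycles`), `matrix`,
#'   `weights_costs`, `weights_benefits` (length `n_cycles`), `arm`,
#'   `n_cycles`, `settings`. `tidy()` returns the long cycle-state table.
#' @examples
#' trace <- run_cohort(nbd_parameters(), "SBC_ALONE")
#' terminal_occupancy(trace, "STOMA")
#' @export
run_cohort <- function(params, arm, start_state = NULL) {
  arm <- match.arg(arm, nbd_arms())
  s <- params$settings
  m <- transition_matrix(params, arm)
  v <- validate_matrix(m)
  if (nrow(v) > 0) {
    stop(sprintf(
      "refusing to run with invalid matrix: %s (row %s)", v$rule[1], v$row[1]
    ), call. = FALSE)
  }
  start_state <- match.arg(start_state %||% arm_start_state(arm), nbd_states())
  n_cycles <- as.integer(round(s$horizon / s$cycle_length))
  occ <- matrix(0, n_cycles + 1, 4, dimnames = list(NULL, nbd_states()))
  occ[1, start_state] <- 1
  for (t in seq_len(n_cycles)) occ[t + 1, ] <- occ[t, ] %*% m
  structure(list(
    occupancy = occ,
    matrix = m,
    weights_costs = discount_weights(n_cycles, s$discount_rate_costs,
      s$cycle_length, s$discount_mode),
    weights_benefits = discount_weights(n_cycles, s$discount_rate_benefits,
      s$cycle_length, s$discount_mode),
    arm = arm, start_state = start_state,
    n_cycles = n_cycles, settings = s
  ), class = "nbd_trace")
}

#' @export
print.nbd_trace <- function(x, ...) {
  cat(sprintf(
    "<nbd_trace> %s: %d cycles of %g years, terminal stoma occupancy %.4f\n",
    x$arm, x$n_cycles, x$settings$cycle_length, terminal_occupancy(x, "STOMA")
  ))
  invisible(x)
}

#' @export
#' @method tidy nbd_trace
tidy.nbd_trace <- function(x, ...) {
  tibble::as_tibble(x$occupancy) |>
    dplyr::mutate(cycle = 0:x$n_cycles, .before = 1) |>
    tidyr::pivot_longer(-"cycle", names_to = "state", values_to = "occupancy") |>
    dplyr::left_join(
      tibble::tibble(
        cycle = 0:(x$n_cycles - 1),
        weight_costs = x$weights_costs,
        weight_benefits = x$weights_benefits
      ),
      by = "cycle"
    )
}

# Occupancy used for within-cycle accrual: start-of-cycle occupancy for
# cycles 0..n-1, optionally averaged with end-of-cycle occupancy when the
# half-cycle correction is enabled.
accrual_occupancy <- function(trace) {
  n <- trace$n_cycles
  occ <- trace$occupancy[seq_len(n), , drop = FALSE]
  if (isTRUE(trace$settings$half_cycle_correction)) {
    occ <- (occ + trace$occupancy[seq_len(n) + 1, , drop = FALSE]) / 2
  }
  occ
}

# Per-cycle event rate by state for one event type (vector over states).
per_cycle_event_rate <- function(params, event) {
  s <- params$settings
  rates <- params$event_rates[params$event_rates$event == event, ]
  per_year <- c(year = 1, month = 12, week = WEEKS_PER_YEAR, day = DAYS_PER_YEAR)
  out <- stats::setNames(rep(0, 4), nbd_states())
  if (nrow(rates) > 0) {
    out[rates$state] <- rates$rate * per_year[rates$unit] * s$cycle_length
  }
  out
}

#' Expected lifetime event count per patient
#'
#' Accrues the expected number of events of one type over the whole trace:
#' occupancy of each state times the state's per-cycle event frequency,
#' optionally weighted by the benefits discount factor (the base-case
#' convention).
#'
#' @param trace An `nbd_trace`.
#' @param params The parameter set used to run the trace.
#' @param event `"FI"`, `"UTI"` or `"HOSP"`.
#' @param discounted Apply discount weights; `NULL` (default) follows
#'   `settings$discount_event_counts`.
#' @param weights Which discount weights to use when discounting.
#' @return Expected lifetime count (scalar).
#' @export
accrue_events <- function(trace, params, event, discounted = NULL,
                          weights = c("benefits", "costs")) {
  event <- match.arg(event, c("FI", "UTI", "HOSP"))
  weights <- match.arg(weights)
  discounted <- discounted %||% trace$settings$discount_event_counts
  rate <- per_cycle_event_rate(params, event)
  occ <- accrual_occupancy(trace)
  w <- if (discounted) {
    if (weights == "benefits") trace$weights_benefits else trace$weights_costs
  } else {
    rep(1, trace$n_cycles)
  }
  sum((occ %*% rate) * w)
}

#' Occupancy of a state at the end of the horizon
#'
#' For the absorbing stoma state this is the cumulative probability of ever
#' undergoing stoma surgery within the horizon. Undiscounted by definition.
#'
#' @inheritParams accrue_events
#' @param state State name.
#' @return Fraction of the cohort (scalar).
#' @export
terminal_occupancy <- function(trace, state) {
  state <- match.arg(state, nbd_states())
  unname(trace$occupancy[trace$n_cycles + 1, state])
}

#' Per-cycle inflow of the cohort into a state
#'
#' The fraction of the cohort entering `state` during each cycle from any
#' other state (used to attach one-off costs such as procedures). Cycle `t`
#' inflow is computed from start-of-cycle-`t` occupancy, so summed inflow
#' into an absorbing state equals its terminal minus initial occupancy.
#'
#' @inheritParams terminal_occupancy
#' @param include_start Count initial occupancy at cycle 0 as an entry
#'   (used for entry costs of the arm's start state).
#' @return A tibble with columns `cycle` (0-based) and `inflow`.
#' @export
state_entry_flows <- function(trace, state, include_start = FALSE) {
  state <- match.arg(state, nbd_states())
  n <- trace$n_cycles
  others <- setdiff(nbd_states(), state)
  inflow <- as.numeric(
    trace$occupancy[seq_len(n), others, drop = FALSE] %*% trace$matrix[others, state]
  )
  if (include_start) inflow[1] <- inflow[1] + trace$occupancy[1, state]
  tibble::tibble(cycle = 0:(n - 1), inflow = inflow)
}

# Discounted state occupancy-cycle sums (internal workhorse shared by the
# QALY and cost accruals).
discounted_occupancy <- function(trace, weights = c("benefits", "costs")) {
  weights <- match.arg(weights)
  w <- if (weights == "benefits") trace$weights_benefits else trace$weights_costs
  colSums(accrual_occupancy(trace) * w)
}
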