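# Model parameter set: health states, transition probabilities, economic
# settings, utilities, event rates and the itemised cost schedule.

DAYS_PER_YEAR <- 365.25
WEEKS_PER_YEAR <- DAYS_PER_YEAR / 7

#' Health states of the bowel-management treatment pathway
#'
#' The model follows the stepped treatment pyramid for neurogenic bowel
#' dysfunction: transanal irrigation (TAI), resumed standard bowel care
#' (RESUME_SBC), surgical interventions (SNS/SARS/ACE, SURGICAL) and stoma
#' surgery (STOMA). Stoma is absorbing: once entered it is never left.
#'
#' @return Character vector of the four state names, in model order.
#' @export
nbd_states <- function() c("TAI", "RESUME_SBC", "SURGICAL", "STOMA")

#' @rdname nbd_states
#' @export
nbd_arms <- function() c("TAI_PLUS_SBC", "SBC_ALONE")

#' Starting state of a treatment arm
#'
#' Patients enter the model after failing standard bowel care for more than
#' six months: the irrigation arm starts in `TAI`, the comparator arm in
#' `RESUME_SBC`.
#'
#' @param arm `"TAI_PLUS_SBC"` or `"SBC_ALONE"`.
#' @return A state name.
#' @export
arm_start_state <- function(arm) {
  arm <- match.arg(arm, nbd_arms())
  if (arm == "TAI_PLUS_SBC") "TAI" else "RESUME_SBC"
}

default_transitions <- function() {
  tibble::tribble(
    ~arm, ~from, ~to, ~p,
    # TAI + SBC arm, per 6-month cycle
    "TAI_PLUS_SBC", "TAI", "TAI", 0.9810,
    "TAI_PLUS_SBC", "TAI", "RESUME_SBC", 0.0069,
    "TAI_PLUS_SBC", "TAI", "SURGICAL", 0.0065,
    "TAI_PLUS_SBC", "TAI", "STOMA", 0.0057,
    "TAI_PLUS_SBC", "RESUME_SBC", "RESUME_SBC", 0.9692,
    "TAI_PLUS_SBC", "RESUME_SBC", "SURGICAL", 0.0113,
    "TAI_PLUS_SBC", "RESUME_SBC", "STOMA", 0.0195,
    "TAI_PLUS_SBC", "SURGICAL", "SURGICAL", 0.9891,
    "TAI_PLUS_SBC", "SURGICAL", "STOMA", 0.0109,
    "TAI_PLUS_SBC", "STOMA", "STOMA", 1.0000,
    # SBC-alone arm: the TAI row is absent (state unreachable)
    "SBC_ALONE", "RESUME_SBC", "RESUME_SBC", 0.9736,
    "SBC_ALONE", "RESUME_SBC", "SURGICAL", 0.0097,
    "SBC_ALONE", "RESUME_SBC", "STOMA", 0.0167,
    "SBC_ALONE", "SURGICAL", "SURGICAL", 0.9831,
    "SBC_ALONE", "SURGICAL", "STOMA", 0.0116,
    "SBC_ALONE", "STOMA", "STOMA", 1.0000
  )
}

default_settings <- function() {
  list(
    cycle_length = 0.5,             # years
    horizon = 37,                   # years; SCI life expectancy at age 30
    discount_rate_costs = 0.035,    # per annum
    discount_rate_benefits = 0.035, # per annum
    discount_mode = "annual_step",  # or "per_cycle_continuous"
    discount_event_counts = TRUE,
    half_cycle_correction = FALSE,
    # Rows short of 1 hand the deficit to the absorbing column
    # ("to_absorbing", consistent with the goal-seek calibration of the
    # surgical retention probability) or are rescaled proportionally
    # ("renormalize").
    row_deficit_policy = "to_absorbing",
    row_sum_tolerance = 0.0055
  )
}

default_utilities <- function() {
  tibble::tibble(
    state = nbd_states(),
    utility = c(0.565, 0.548, 0.548, 0.505)
  )
}

# Per-event utility decrements, applied for a finite episode duration.
default_decrements <- function() {
  tibble::tribble(
    ~event, ~decrement, ~episode_days,
    "UTI", -0.060, 7,
    "HOSP", -0.100, 14
  )
}

# Event frequencies by occupied state. Fecal incontinence is recorded per
# week; UTIs and hospitalizations per year. States without a row accrue no
# events.
default_event_rates <- function() {
  tibble::tribble(
    ~event, ~state, ~rate, ~unit,
    "FI", "TAI", 1.5, "week",
    "FI", "RESUME_SBC", 3.5, "week",
    "UTI", "TAI", 0.67, "year",
    "UTI", "RESUME_SBC", 1.37, "year",
    "HOSP", "TAI", 0.28, "year",
    "HOSP", "RESUME_SBC", 1.37, "year"
  )
}

# Itemised cost schedule. `quantity` is uses per `unit` period; attachment
# is state_recurring (applies to occupancy), state_entry (one-off on entry,
# including cycle-0 start), or per_event (per discounted event count).
# `proportion` is the fraction of the occupying cohort (or the event/
# procedure mix weight) the item applies to. `list_price` marks tariff/BNF
# pack prices that are held fixed in probabilistic sensitivity analysis.
default_cost_items <- function() {
  third <- 1 / 3
  tibble::tribble(
    ~item, ~group, ~pack_cost, ~pack_size, ~quantity, ~unit, ~attachment, ~target, ~proportion, ~list_price,
    "fybogel", "sbc_drugs", 2.29, 30, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "docusate", "sbc_drugs", 6.98, 100, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "bisacodyl", "sbc_drugs", 3.43, 100, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "movicol", "sbc_drugs", 11.13, 50, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "supp_glycerine", "sbc_drugs", 1.94, 12, 0.5, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "supp_bisacodyl", "sbc_drugs", 1.57, 12, 0.5, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "norgalax", "sbc_drugs", 0.66, 1, 0.5, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "anal_plug_tai", "continence", 44.89, 20, 1, "day", "state_recurring", "TAI", 1, TRUE,
    "anal_plug_sbc", "continence", 44.89, 20, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "anal_plug_fi", "continence", 44.89, 20, 1, "event", "per_event", "FI", 1, TRUE,
    "pad_tai", "continence", 5.95, 7, 1, "day", "state_recurring", "TAI", 1, TRUE,
    "pad_sbc", "continence", 5.95, 7, 1, "day", "state_recurring", "RESUME_SBC", 1, TRUE,
    "pad_fi", "continence", 5.95, 7, 1, "event", "per_event", "FI", 1, TRUE,
    "tai_system", "tai", 74.78, 1, 1, "cycle", "state_recurring", "TAI", 1, TRUE,
    "tai_catheters", "tai", 130.33, 1, 1, "month", "state_recurring", "TAI", 1, TRUE,
    "tai_consultation", "tai", 142.00, 1, 1, "one_off", "state_entry", "TAI", 1, FALSE,
    "tai_phone_calls", "tai", 100.00, 1, 3, "one_off", "state_entry", "TAI", 1, FALSE,
    "sns_procedure", "surgical", 9368.00, 1, 1, "one_off", "state_entry", "SURGICAL", third, FALSE,
    "sars_procedure", "surgical", 7770.00, 1, 1, "one_off", "state_entry", "SURGICAL", third, FALSE,
    "ace_procedure", "surgical", 3870.33, 1, 1, "one_off", "state_entry", "SURGICAL", third, FALSE,
    "sns_followup", "surgical", 6286.00, 1, 1 / 7, "year", "state_recurring", "SURGICAL", third, FALSE,
    "sars_followup", "surgical", 118.92, 1, 0.5, "month", "state_recurring", "SURGICAL", third, FALSE,
    "ace_followup", "surgical", 118.92, 1, 0.5, "month", "state_recurring", "SURGICAL", third, FALSE,
    "stoma_surgery", "stoma", 7459.76, 1, 1, "one_off", "state_entry", "STOMA", 1, FALSE,
    "colostomy_bag", "stoma", 87.00, 30, 2, "day", "state_recurring", "STOMA", 1, TRUE,
    "stoma_belt", "stoma", 6.78, 1, 1, "month", "state_recurring", "STOMA", 1, TRUE,
    "skin_barrier", "stoma", 22.24, 30, 2, "day", "state_recurring", "STOMA", 1, TRUE,
    "adhesive_remover", "stoma", 14.96, 30, 2, "day", "state_recurring", "STOMA", 1, TRUE,
    "peristomal_complications", "stoma", 34.89, 1, 0.61, "year", "state_recurring", "STOMA", 1, FALSE,
    "hernia_complication", "stoma", 3355.69, 1, 0.18, "four_months", "state_recurring", "STOMA", 1, FALSE,
    "consultant_tai", "hcp", 142.00, 1, 0.88, "year", "state_recurring", "TAI", 1, FALSE,
    "consultant_sbc", "hcp", 142.00, 1, 1.04, "year", "state_recurring", "RESUME_SBC", 1, FALSE,
    "dietician_tai", "hcp", 37.00, 1, 0.19, "year", "state_recurring", "TAI", 1, FALSE,
    "dietician_sbc", "hcp", 37.00, 1, 0.57, "year", "state_recurring", "RESUME_SBC", 1, FALSE,
    "gp_tai", "hcp", 234.00, 1, 2.89, "year", "state_recurring", "TAI", 1, FALSE,
    "gp_sbc", "hcp", 234.00, 1, 3.75, "year", "state_recurring", "RESUME_SBC", 1, FALSE,
    # caregiver: hourly wage x hours/day x share of patients with a carer
    "caregiver_tai", "caregiver", 24.00, 1, 19 / 60, "day", "state_recurring", "TAI", 0.25, FALSE,
    "caregiver_sbc", "caregiver", 24.00, 1, 26 / 60, "day", "state_recurring", "RESUME_SBC", 0.45, FALSE,
    "uti_treatment", "adverse_events", 167.77, 1, 1, "event", "per_event", "UTI", 1, FALSE,
    # hospitalization admission-cause mix: equal weights over the three
    # acute admission costs; pressure-ulcer management is retained at
    # weight 0 (long-term management cost, not an acute admission)
    "hosp_gi_infection", "adverse_events", 1998.84, 1, 1, "event", "per_event", "HOSP", third, FALSE,
    "hosp_pressure_ulcer", "adverse_events", 24214.00, 1, 1, "event", "per_event", "HOSP", 0, FALSE,
    "hosp_falls_trauma", "adverse_events", 2326.32, 1, 1, "event", "per_event", "HOSP", third, FALSE,
    "hosp_abdominal_pain", "adverse_events", 1432.09, 1, 1, "event", "per_event", "HOSP", third, FALSE
  )
}

#' Assemble the full model parameter set
#'
#' Returns the canonical parameter set of the cost-utility model: per-arm
#' six-month transition probabilities, economic settings (cycle length 0.5
#' years, 37-year horizon, 3.5% p.a. discounting of costs and benefits),
#' health-state utility values with per-event decrements, state-specific
#' event frequencies, and the itemised cost schedule. Any component can be
#' replaced or partially overridden.
#'
#' @param transitions Data frame with columns `arm`, `from`, `to`, `p`
#'   replacing the default transition probabilities.
#' @param settings Named list merged over the default economic settings.
#' @param utilities Data frame with columns `state`, `utility`.
#' @param decrements Data frame with columns `event`, `decrement`,
#'   `episode_days`.
#' @param event_rates Data frame with columns `event`, `state`, `rate`,
#'   `unit`.
#' @param cost_items Data frame matching the default cost schedule columns.
#' @param fi_rate_period `"week"` or `"month"`: period of the recorded
#'   fecal-incontinence frequencies (1.5 TAI, 3.5 SBC). The printed lifetime
#'   totals are consistent with the weekly reading, which is the default.
#' @param validate Validate the assembled set (default `TRUE`).
#'
#' @return An object of class `nbd_parameters`: a named list with elements
#'   `transitions`, `settings`, `utilities`, `decrements`, `event_rates`,
#'   `cost_items`.
#' @examples
#' params <- nbd_parameters()
#' transition_matrix(params, "TAI_PLUS_SBC")["TAI", ]
#' @export
nbd_parameters <- function(transitions = NULL, settings = NULL,
                           utilities = NULL, decrements = NULL,
                           event_rates = NULL, cost_items = NULL,
                           fi_rate_period = c("week", "month"),
                           validate = TRUE) {
  fi_rate_period <- match.arg(fi_rate_period)
  params <- structure(list(
    transitions = if (is.null(transitions)) default_transitions() else tibble::as_tibble(transitions),
    settings = utils::modifyList(default_settings(), settings %||% list()),
    utilities = if (is.null(utilities)) default_utilities() else tibble::as_tibble(utilities),
    decrements = if (is.null(decrements)) default_decrements() else tibble::as_tibble(decrements),
    event_rates = if (is.null(event_rates)) default_event_rates() else tibble::as_tibble(event_rates),
    cost_items = if (is.null(cost_items)) default_cost_items() else tibble::as_tibble(cost_items)
  ), class = "nbd_parameters")
  if (is.null(event_rates) && fi_rate_period == "month") {
    params$event_rates$unit[params$event_rates$event == "FI"] <- "month"
  }
  if (validate) validate_parameters(params)
  params
}

#' @export
print.nbd_parameters <- function(x, ...) {
  s <- x$settings
  cat("<nbd_parameters>\n")
  cat(sprintf(
    "  %d-year horizon, %g-year cycles (%d cycles), discounting %.1f%%/%.1f%% p.a. (%s)\n",
    s$horizon, s$cycle_length, as.integer(round(s$horizon / s$cycle_length)),
    100 * s$discount_rate_costs, 100 * s$discount_rate_benefits, s$discount_mode
  ))
  cat(sprintf(
    "  %d transition entries, %d cost items, %d event-rate rows\n",
    nrow(x$transitions), nrow(x$cost_items), nrow(x$event_rates)
  ))
  invisible(x)
}

#' Build the per-cycle transition matrix of one arm
#'
#' Assembles the square transition matrix over the model states from the
#' transition table, resolving rows whose printed probabilities do not sum
#' exactly to 1 according to the row-deficit policy: `"to_absorbing"`
#' (default) adds the deficit to the absorbing stoma column, the reading
#' consistent with the goal-seek calibration of the surgical retention
#' probability; `"renormalize"` rescales the row proportionally. In the
#' SBC-alone arm the TAI state is unreachable and its row is the identity
#' row.
#'
#' @param params An `nbd_parameters` object.
#' @param arm Arm name.
#' @param policy Override of `params$settings$row_deficit_policy`.
#' @return A numeric matrix with dimnames over [nbd_states()].
#' @export
transition_matrix <- function(params, arm, policy = NULL) {
  arm <- match.arg(arm, nbd_arms())
  policy <- policy %||% params$settings$row_deficit_policy
  policy <- match.arg(policy, c("to_absorbing", "renormalize", "none"))
  states <- nbd_states()
  m <- matrix(0, 4, 4, dimnames = list(states, states))
  tr <- params$transitions[params$transitions$arm == arm, ]
  for (i in seq_len(nrow(tr))) m[tr$from[i], tr$to[i]] <- tr$p[i]
  # unreachable / undefined rows become identity rows
  defined <- rownames(m) %in% unique(tr$from)
  diag(m)[!defined] <- 1
  if (policy != "none") {
    for (s in states[defined]) {
      rs <- sum(m[s, ])
      if (abs(rs - 1) < .Machine$double.eps * 8) next
      if (policy == "renormalize") {
        m[s, ] <- m[s, ] / rs
      } else {
        m[s, "STOMA"] <- m[s, "STOMA"] + (1 - rs)
      }
    }
  }
  m
}

#' Validate a transition matrix
#'
#' Checks the structural invariants: entries in `[0, 1]`, rows summing to 1
#' within tolerance, and the absorbing stoma row equal to the identity row.
#' Violations are reported, not thrown.
#'
#' @param m Square numeric matrix with state dimnames.
#' @param tolerance Allowed deviation of a row sum from 1.
#' @return A tibble with columns `row`, `column`, `rule`, `value`; zero rows
#'   when all invariants hold.
#' @export
validate_matrix <- function(m, tolerance = 1e-6) {
  states <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] < 0 || m[i, j] > 1) {
        out[[length(out) + 1]] <- tibble::tibble(
          row = states[i], column = states[j],
          rule = "entry_in_unit_interval", value = m[i, j]
        )
      }
    }
    rs <- sum(m[i, ])
    if (abs(rs - 1) > tolerance) {
      out[[length(out) + 1]] <- tibble::tibble(
        row = states[i], column = NA_character_,
        rule = "row_sums_to_one", value = rs
      )
    }
  }
  absorbing <- rep(0, ncol(m))
  absorbing[match("STOMA", states)] <- 1
  if (!isTRUE(all.equal(unname(m["STOMA", ]), absorbing, tolerance = 1e-12))) {
    out[[length(out) + 1]] <- tibble::tibble(
      row = "STOMA", column = NA_character_,
      rule = "absorbing_row_is_identity", value = sum(m["STOMA", ]) - 1
    )
  }
  if (length(out) == 0) {
    tibble::tibble(
      row = character(), column = character(),
      rule = character(), value = numeric()
    )
  } else {
    dplyr::bind_rows(out)
  }
}

validate_parameters <- function(params) {
  s <- params$settings
  stopifnot(
    s$cycle_length > 0, s$horizon > 0,
    s$discount_rate_costs >= 0, s$discount_rate_costs < 1,
    s$discount_rate_benefits >= 0, s$discount_rate_benefits < 1
  )
  n_cycles <- s$horizon / s$cycle_length
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("horizon must be an integer multiple of cycle_length", call. = FALSE)
  }
  if (any(params$transitions$p < 0 | params$transitions$p > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  # raw row sums must be within the configured print-rounding tolerance
  sums <- params$transitions |>
    dplyr::summarise(s = sum(.data$p), .by = c("arm", "from"))
  bad <- sums[abs(sums$s - 1) > s$row_sum_tolerance, ]
  if (nrow(bad) > 0) {
    stop(sprintf(
      "transition row %s/%s sums to %.4f, outside tolerance %.4g of 1",
      bad$arm[1], bad$from[1], bad$s[1], s$row_sum_tolerance
    ), call. = FALSE)
  }
  for (arm in unique(params$transitions$arm)) {
    v <- validate_matrix(transition_matrix(params, arm))
    if (nrow(v) > 0) {
      stop(sprintf(
        "invalid %s transition matrix after deficit resolution: %s (row %s)",
        arm, v$rule[1], v$row[1]
      ), call. = FALSE)
    }
  }
  with(params$utilities, stopifnot(all(utility >= 0 & utility <= 1)))
  with(params$decrements, stopifnot(all(decrement <= 0), all(episode_days >= 0)))
  with(params$event_rates, stopifnot(all(rate >= 0)))
  with(params$cost_items, stopifnot(
    all(pack_cost >= 0), all(pack_size >= 1),
    all(proportion >= 0 & proportion <= 1), all(quantity >= 0)
  ))
  bad_target <- setdiff(
    params$cost_items$target[params$cost_items$attachment != "per_event"],
    nbd_states()
  )
  if (length(bad_target) > 0) {
    stop("cost item attached to unknown state: ", bad_target[1], call. = FALSE)
  }
  invisible(params)
}

# Write the policy-resolved transition probabilities back into the
# transition table, so downstream perturbation (sensitivity analysis)
# operates on rows that sum exactly to 1.
resolve_transitions <- function(params) {
  tr <- params$transitions
  for (arm in unique(tr$arm)) {
    m <- transition_matrix(params, arm)
    sel <- which(tr$arm == arm)
    tr$p[sel] <- m[cbind(tr$from[sel], tr$to[sel])]
  }
  params$transitions <- tr
  params
}

#' Tidy table of every scalar model parameter
#'
#' Enumerates the individual numeric parameters of the model — off-diagonal
#' transition probabilities, state utilities, event-decrement magnitudes,
#' event rates, cost-item prices, usage frequencies and applied proportions
#' — with a class label used to pick perturbation rules and sampling
#' distributions, and a flag marking tariff list prices excluded from
#' probabilistic sampling. `set_parameter()` is the inverse: it writes a
#' value back into a parameter set by name.
#'
#' @param params An `nbd_parameters` object.
#' @return A tibble with columns `parameter`, `class` (one of
#'   `"probability"`, `"utility"`, `"decrement"`, `"rate"`, `"cost"`,
#'   `"proportion"`), `value`, `sampled`.
#' @export
parameter_table <- function(params) {
  tr <- params$transitions |>
    dplyr::filter(.data$from != "STOMA") |>
    dplyr::transmute(
      parameter = paste("p", .data$arm, .data$from, .data$to, sep = "."),
      class = "probability", value = .data$p, sampled = TRUE
    )
  ut <- params$utilities |>
    dplyr::transmute(
      parameter = paste("utility", .data$state, sep = "."),
      class = "utility", value = .data$utility, sampled = TRUE
    )
  de <- params$decrements |>
    dplyr::transmute(
      parameter = paste("decrement", .data$event, sep = "."),
      class = "decrement", value = .data$decrement, sampled = TRUE
    )
  ra <- params$event_rates |>
    dplyr::transmute(
      parameter = paste("rate", .data$event, .data$state, sep = "."),
      class = "rate", value = .data$rate, sampled = TRUE
    )
  ci <- params$cost_items
  co <- dplyr::bind_rows(
    tibble::tibble(
      parameter = paste("cost", ci$item, sep = "."),
      class = "cost", value = ci$pack_cost, sampled = !ci$list_price
    ),
    tibble::tibble(
      parameter = paste("quantity", ci$item, sep = "."),
      class = "rate", value = ci$quantity, sampled = ci$unit != "event"
    )[ci$attachment == "state_recurring" & ci$quantity > 0, ],
    tibble::tibble(
      parameter = paste("proportion", ci$item, sep = "."),
      class = "proportion", value = ci$proportion, sampled = TRUE
    )[ci$proportion > 0 & ci$proportion < 1, ]
  )
  dplyr::bind_rows(tr, ut, de, ra, co)
}

#' @rdname parameter_table
#' @param parameter Parameter name as printed by `parameter_table()`.
#' @param value New numeric value.
#' @export
set_parameter <- function(params, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "p") {
    i <- with(params$transitions, which(
      arm == parts[2] & from == parts[3] & to == parts[4]
    ))
    if (length(i) != 1) stop("unknown transition parameter: ", parameter, call. = FALSE)
    params$transitions$p[i] <- min(1, max(0, value))
    # keep the row on the simplex: rescale it proportionally
    row <- with(params$transitions, which(arm == parts[2] & from == parts[3]))
    params$transitions$p[row] <- params$transitions$p[row] /
      sum(params$transitions$p[row])
  } else if (kind == "utility") {
    i <- which(params$utilities$state == parts[2])
    params$utilities$utility[i] <- min(1, max(0, value))
  } else if (kind == "decrement") {
    i <- which(params$decrements$event == parts[2])
    params$decrements$decrement[i] <- min(0, value)
  } else if (kind == "rate") {
    i <- with(params$event_rates, which(event == parts[2] & state == parts[3]))
    params$event_rates$rate[i] <- max(0, value)
  } else if (kind %in% c("cost", "quantity", "proportion")) {
    i <- which(params$cost_items$item == paste(parts[-1], collapse = "."))
    if (length(i) != 1) stop("unknown cost item: ", parameter, call. = FALSE)
    col <- c(cost = "pack_cost", quantity = "quantity", proportion = "proportion")[[kind]]
    params$cost_items[[col]][i] <-
      if (kind == "proportion") min(1, max(0, value)) else max(0, value)
  } else {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  params
}

#' Read and write the model configuration file
#'
#' The full parameter set is carried by a human-readable YAML file with a
#' versioned schema; the shipped canonical configuration
#' (`system.file("extdata", "nbd_model.yaml", package = "nbdcea")`) holds
#' the published model inputs. `write_model_config()` followed by
#' `read_model_config()` round-trips a parameter set exactly.
#'
#' @param path File path.
#' @return `read_model_config()` returns an `nbd_parameters` object;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema) || raw$schema != "nbdcea-1") {
    stop("unrecognised configuration schema: ", raw$schema %||% "<missing>", call. = FALSE)
  }
  for (key in c("settings", "transitions", "utilities", "decrements", "event_rates", "cost_items")) {
    if (is.null(raw[[key]])) stop("configuration key missing: ", key, call. = FALSE)
  }
  as_rows <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  nbd_parameters(
    transitions = as_rows(raw$transitions),
    settings = raw$settings,
    utilities = as_rows(raw$utilities),
    decrements = as_rows(raw$decrements),
    event_rates = as_rows(raw$event_rates),
    cost_items = as_rows(raw$cost_items)
  )
}

#' @rdname read_model_config
#' @param params An `nbd_parameters` object.
#' @export
write_model_config <- function(params, path) {
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  yaml::write_yaml(list(
    schema = "nbdcea-1",
    settings = params$settings,
    transitions = row_list(params$transitions),
    utilities = row_list(params$utilities),
    decrements = row_list(params$decrements),
    event_rates = row_list(params$event_rates),
    cost_items = row_list(params$cost_items)
  ), path, precision = 12)
  invisible(path)
}

#' Default model configuration shipped with the package
#'
#' @return Path to the canonical YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "nbd_model.yaml", package = "nbdcea", mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
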