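# Sensitivity analysis: one-way deterministic (tornado) and probabilistic
# (CE plane, CEAC).

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full cost-utility comparison with each scalar model
#' parameter set to a low and a high value — health-state utilities varied
#' by an absolute `± utility_abs` (0.02 by default), every other input by a
#' relative `± rel` (25%) — holding all else at base case. Probabilities
#' are clamped to `[0, 1]` and their transition row re-closed through the
#' diagonal. Results are ranked by the spread of the chosen incremental
#' outcome, incremental net monetary benefit at `wtp` by default.
#'
#' @param params Base parameter set.
#' @param rel Relative perturbation for non-utility parameters.
#' @param utility_abs Absolute perturbation for state utilities.
#' @param wtp Willingness-to-pay threshold (GBP/QALY) for net monetary
#'   benefit.
#' @param measure Ranking outcome: incremental net monetary benefit
#'   (`"nmb"`), incremental cost, or incremental QALYs.
#' @return An object of class `nbd_dsa`: tibble with one row per parameter
#'   (`parameter`, `class`, `base_value`, `value_low`, `value_high`,
#'   `result_low`, `result_high`, `result_base`, `spread`), sorted by
#'   decreasing spread. Plot with `autoplot()` for a tornado diagram.
#' @export
one_way_dsa <- function(params, rel = 0.25, utility_abs = 0.02,
                        wtp = 30000, measure = c("nmb", "cost", "qalys")) {
  measure <- match.arg(measure)
  outcome <- function(p) {
    fit <- run_base_case(p)
    switch(measure,
      nmb = wtp * fit$incremental$delta_qalys - fit$incremental$delta_cost,
      cost = fit$incremental$delta_cost,
      qalys = fit$incremental$delta_qalys
    )
  }
  params <- resolve_transitions(params)
  ptab <- parameter_table(params)
  # retention (diagonal) probabilities are row complements, not free inputs:
  # the one-way analysis perturbs the off-diagonal transition entries only
  diag_p <- grepl("^p\\.[^.]+\\.([^.]+)\\.\\1$", ptab$parameter)
  ptab <- ptab[!diag_p, ]
  base_result <- outcome(params)
  res <- purrr::map_dfr(seq_len(nrow(ptab)), function(i) {
    p0 <- ptab$value[i]
    bounds <- if (ptab$class[i] == "utility") {
      c(max(0, p0 - utility_abs), min(1, p0 + utility_abs))
    } else if (ptab$class[i] == "probability") {
      c(max(0, p0 * (1 - rel)), min(1, p0 * (1 + rel)))
    } else {
      sort(c(p0 * (1 - rel), p0 * (1 + rel)))
    }
    lo <- outcome(set_parameter(params, ptab$parameter[i], bounds[1]))
    hi <- outcome(set_parameter(params, ptab$parameter[i], bounds[2]))
    tibble::tibble(
      parameter = ptab$parameter[i], class = ptab$class[i],
      base_value = p0, value_low = bounds[1], value_high = bounds[2],
      result_low = lo, result_high = hi, result_base = base_result,
      spread = abs(hi - lo)
    )
  })
  structure(dplyr::arrange(res, dplyr::desc(.data$spread)),
    class = c("nbd_dsa", class(res)))
}

# Sample one parameter's n draws: beta for quantities living on [0, 1]
# (probabilities, utilities, cohort proportions), gamma for nonnegative
# ones (rates, costs), moment-matched to (mean, se = se_rule * mean).
# Decrements are sampled on their magnitude and negated. Falls back to a
# clamped normal when moment matching is infeasible.
sample_parameter <- function(n, mean, class, se_rule) {
  se <- se_rule * abs(mean)
  if (se == 0 || mean == 0) {
    return(rep(mean, n))
  }
  v <- se^2
  if (class %in% c("probability", "utility", "proportion")) {
    m <- abs(mean)
    if (v < m * (1 - m)) {
      nu <- m * (1 - m) / v - 1
      stats::rbeta(n, m * nu, (1 - m) * nu)
    } else {
      pmin(1, pmax(0, stats::rnorm(n, m, se)))
    }
  } else {
    m <- abs(mean)
    draws <- stats::rgamma(n, shape = (m / se)^2, scale = v / m)
    if (mean < 0) -draws else draws
  }
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Samples every non-fixed model parameter independently from a
#' moment-matched distribution — beta for parameters on the unit interval,
#' gamma for nonnegative ones — with standard error equal to `se_rule`
#' times the mean. Tariff list prices are held fixed. Transition rows are
#' re-closed through their diagonal after sampling. The draw matrix is
#' fully reproducible from `seed`.
#'
#' @param params Base parameter set.
#' @param n_draws Number of draws.
#' @param se_rule Standard error as a fraction of the mean (0.10 in the
#'   base analysis).
#' @param seed Integer seed.
#' @return A list with `values` (matrix `n_draws x n_parameters`) and
#'   `parameters` (the sampled subset of [parameter_table()]).
#' @export
draw_parameters <- function(params, n_draws, se_rule = 0.10, seed = 1) {
  params <- resolve_transitions(params)
  ptab <- parameter_table(params)
  ptab <- ptab[ptab$sampled, ]
  set.seed(seed)
  values <- vapply(
    seq_len(nrow(ptab)),
    function(j) sample_parameter(n_draws, ptab$value[j], ptab$class[j], se_rule),
    numeric(n_draws)
  )
  if (n_draws == 1) values <- matrix(values, nrow = 1)
  colnames(values) <- ptab$parameter
  list(values = values, parameters = ptab)
}

# Apply one row of a draw matrix to the base parameter set. Transition
# entries are written in bulk and each row renormalized once afterwards;
# the remaining parameters go through set_parameter().
apply_draw <- function(params, draws, i) {
  vals <- draws$values[i, ]
  names(vals) <- draws$parameters$parameter
  is_p <- startsWith(names(vals), "p.")
  if (any(is_p)) {
    tr <- params$transitions
    key <- paste(tr$arm, tr$from, tr$to, sep = ".")
    idx <- match(sub("^p\\.", "", names(vals)[is_p]), key)
    stopifnot(!anyNA(idx))
    tr$p[idx] <- pmin(1, pmax(0, vals[is_p]))
    tr$p <- tr$p / stats::ave(tr$p, tr$arm, tr$from, FUN = sum)
    params$transitions <- tr
  }
  for (j in which(!is_p)) {
    params <- set_parameter(params, names(vals)[j], vals[[j]])
  }
  params
}

ce_quadrant <- function(delta_cost, delta_qalys) {
  dplyr::case_when(
    delta_cost < 0 & delta_qalys >= 0 ~ "SE_dominant",
    delta_cost >= 0 & delta_qalys >= 0 ~ "NE",
    delta_cost < 0 & delta_qalys < 0 ~ "SW",
    TRUE ~ "NW_dominated"
  )
}

#' Probabilistic sensitivity analysis
#'
#' Runs the cost-utility model on `n_draws` sampled parameter sets (see
#' [draw_parameters()]); each draw evaluates both arms under the same
#' sampled parameters, giving one incremental cost / incremental QALY point
#' on the cost-effectiveness plane.
#'
#' @inheritParams draw_parameters
#' @return An object of class `nbd_psa`: list with `points` (tibble `draw`,
#'   `delta_cost`, `delta_qalys`, `quadrant`) and `summary` (one-row
#'   tibble: means, fraction cost-saving, fraction per quadrant).
#'   `tidy()` returns the points, `glance()` the summary; `autoplot()`
#'   draws the CE plane.
#' @examples
#' psa <- run_psa(nbd_parameters(), n_draws = 20, seed = 42)
#' glance(psa)
#' @export
run_psa <- function(params, n_draws = 1000, se_rule = 0.10, seed = 1) {
  params <- resolve_transitions(params)
  draws <- draw_parameters(params, n_draws, se_rule, seed)
  points <- purrr::map_dfr(seq_len(n_draws), function(i) {
    p_i <- apply_draw(params, draws, i)
    inc <- incremental_analysis(
      run_arm(p_i, "TAI_PLUS_SBC"), run_arm(p_i, "SBC_ALONE")
    )
    tibble::tibble(
      draw = i, delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys
    )
  })
  points$quadrant <- ce_quadrant(points$delta_cost, points$delta_qalys)
  summary <- tibble::tibble(
    n_draws = n_draws,
    mean_delta_cost = mean(points$delta_cost),
    mean_delta_qalys = mean(points$delta_qalys),
    fraction_cost_saving = mean(points$delta_cost < 0),
    fraction_dominant = mean(points$quadrant == "SE_dominant"),
    fraction_ne = mean(points$quadrant == "NE"),
    fraction_sw = mean(points$quadrant == "SW"),
    fraction_dominated = mean(points$quadrant == "NW_dominated")
  )
  structure(list(
    points = points, summary = summary,
    spec = list(n_draws = n_draws, se_rule = se_rule, seed = seed)
  ), class = "nbd_psa")
}

#' @export
print.nbd_psa <- function(x, ...) {
  cat(sprintf(
    "<nbd_psa> %d draws (SE = %.0f%% of mean, seed %d): %.1f%% cost-saving, mean dCost %.0f GBP, mean dQALY %.3f\n",
    x$spec$n_draws, 100 * x$spec$se_rule, x$spec$seed,
    100 * x$summary$fraction_cost_saving,
    x$summary$mean_delta_cost, x$summary$mean_delta_qalys
  ))
  invisible(x)
}

#' @export
#' @method tidy nbd_psa
tidy.nbd_psa <- function(x, ...) x$points

#' @export
#' @method glance nbd_psa
glance.nbd_psa <- function(x, ...) x$summary

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with positive
#' incremental net monetary benefit `wtp * dQALY - dCost`.
#'
#' @param psa An `nbd_psa` object (or a data frame with `delta_cost` and
#'   `delta_qalys`).
#' @param wtp_grid Vector of willingness-to-pay thresholds (GBP/QALY).
#' @return An object of class `nbd_ceac`: tibble with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be nonempty", call. = FALSE)
  points <- if (inherits(psa, "nbd_psa")) psa$points else tibble::as_tibble(psa)
  res <- tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(
      wtp_grid,
      function(l) mean(l * points$delta_qalys - points$delta_cost > 0),
      0
    )
  )
  structure(res, class = c("nbd_ceac", class(res)))
}
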