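# Independent brute-force oracles used to cross-check the cohort engine.

# Patient-level microsimulation of a Markov chain: direct per-patient
# sampling, sharing no code with the cohort engine.
simulate_patients <- function(m, start, n_cycles, n_patients, seed = 1) {
  set.seed(seed)
  k <- nrow(m)
  occ <- matrix(0, n_cycles + 1, k)
  state <- rep(start, n_patients)
  occ[1, ] <- tabulate(state, k) / n_patients
  for (t in seq_len(n_cycles)) {
    new_state <- state
    for (s in seq_len(k)) {
      idx <- which(state == s)
      if (length(idx) > 0) {
        new_state[idx] <- sample.int(k, length(idx), replace = TRUE, prob = m[s, ])
      }
    }
    state <- new_state
    occ[t + 1, ] <- tabulate(state, k) / n_patients
  }
  occ
}

# Parameter set with arbitrary TAI-arm transition rows (other components at
# defaults); rows are given over the four states in model order.
params_with_matrix <- function(rows, settings = NULL) {
  states <- nbd_states()
  tr <- do.call(rbind, lapply(seq_along(rows), function(i) {
    tibble::tibble(
      arm = "TAI_PLUS_SBC", from = states[i], to = states,
      p = rows[[i]]
    )
  }))
  tr <- tr[tr$p > 0 | tr$from == tr$to, ]
  tr <- dplyr::bind_rows(
    tr,
    default_transitions()[default_transitions()$arm == "SBC_ALONE", ]
  )
  nbd_parameters(transitions = tr, settings = settings)
}

# Random valid transition rows (Dirichlet-style) with absorbing stoma.
random_rows <- function() {
  rows <- lapply(1:3, function(i) {
    x <- stats::rgamma(4, shape = c(30, 1, 1, 1))
    x / sum(x)
  })
  c(rows, list(c(0, 0, 0, 1)))
}
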