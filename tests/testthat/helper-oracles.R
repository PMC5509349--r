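# Closed-form oracle for the two-state (binary plastic) model, derived
# independently from the balance equation p*t_pot*psi_weak =
# (1-p)*t_dep*psi_strong.  Used to cross-check the matrix-based code path.
binary_oracle <- function(t_pot, t_dep, p) {
  denom <- p * t_pot + (1 - p) * t_dep
  psi_s <- p * t_pot / denom
  list(
    occupancy = c(1 - psi_s, psi_s),
    signal = 2 * psi_s - 1,
    noise = 4 * p * (1 - p) * t_pot * t_dep / denom,
    sensitivity = 2 * t_pot * t_dep / denom^2,
    precision = 1 / (2 * p * (1 - p) * denom),
    adaptability = denom,
    eff_pot = t_pot,
    eff_dep = t_dep
  )
}

# Random valid free-rate vector for the symmetric family: per-source
# outflow kept below 1 by scaling, independent of the package's rejection
# sampler.
random_valid_params <- function(n_states) {
  idx <- rate_index(n_states)
  raw <- stats::runif(nrow(idx))
  for (s in unique(idx$source)) {
    rows <- idx$source == s
    tot <- sum(raw[rows])
    if (tot > 1) raw[rows] <- raw[rows] * stats::runif(1) / tot
  }
  raw
}

ladder_params <- function(q, n_states) {
  idx <- rate_index(n_states)
  ifelse(idx$dest == idx$source + 1L, q, 0)
}

# A small optimized "superior" N=4 model used by comparison tests
# (computed once per test run; deterministic given the seed).
superior_n4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fr <- random_frontier(4, 20000, n_bins = 10, seed = 2)
      rf <- refine_frontier(fr, iterations = 2, seed = 3)
      cache <<- build_symmetric_model(
        rf$params[[which.max(rf$objective)]], 4)
    }
    cache
  }
})
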