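#' Average transition matrix at a fixed reward probability
#'
#' The per-trial dynamics average over reward outcomes: with reward
#' probability `p_r` the potentiation matrix applies, otherwise the
#' depression matrix, giving the column-stochastic average
#' `p_r * T_pot + (1 - p_r) * T_dep`.
#'
#' @param model A `metaplastic_model`.
#' @param p_r Reward probability in `[0, 1]`.
#' @return Column-stochastic `N x N` matrix.
#' @export
average_transition <- function(model, p_r) {
  check_p_r(p_r)
  p_r * model$potentiation + (1 - p_r) * model$depression
}

check_p_r <- function(p_r) {
  if (length(p_r) != 1 || is.na(p_r) || p_r < 0 || p_r > 1) {
    stop("p_r must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(p_r)
}

# Eigenvalue-gap tolerance below which the unit eigenvalue is considered
# non-unique (absorbing or disconnected chain).
.unit_gap_tol <- 1e-8

sorted_eigen_moduli <- function(m) {
  sort(Mod(eigen(m, only.values = TRUE)$values), decreasing = TRUE)
}

#' Steady-state occupancy of the averaged chain
#'
#' Computes the Perron eigenvector (eigenvalue 1) of the averaged
#' transition matrix: the stationary distribution of synapses over
#' meta-states at fixed reward probability. Uniqueness of the unit
#' eigenvalue is checked (gap at least 1e-8 in modulus); degenerate chains
#' (e.g. zero rates, or absorbing ends at `p_r` of 0 or 1 in some
#' topologies) are rejected.
#'
#' @inheritParams average_transition
#' @return Nonnegative numeric vector summing to 1.
#' @export
steady_state <- function(model, p_r) {
  m <- average_transition(model, p_r)
  n <- nrow(m)
  eg <- eigen(m)
  mods <- Mod(eg$values)
  near_unit <- sum(mods > 1 - .unit_gap_tol)
  if (near_unit != 1) {
    stop(sprintf(
      "non-unique steady state: %d eigenvalues within %g of modulus 1",
      near_unit, .unit_gap_tol), call. = FALSE)
  }
  i <- which.max(mods)
  v <- Re(eg$vectors[, i])
  if (sum(v) < 0) v <- -v
  # fall back to a bordered linear solve when the eigenvector is inaccurate
  if (any(v < -1e-10) || max(abs(m %*% v - v)) > 1e-10 * max(abs(v))) {
    b <- m - diag(n)
    b[n, ] <- 1
    rhs <- c(rep(0, n - 1), 1)
    v <- solve(b, rhs)
  }
  v <- pmax(v, 0)
  v / sum(v)
}

#' Signal carried by an occupancy
#'
#' The signal is the efficacy-weighted occupancy: for binary efficacies it
#' equals the fraction of synapses in strong meta-states minus the fraction
#' in weak meta-states, the quantity that encodes the reward-probability
#' estimate.
#'
#' @param occupancy Numeric occupancy vector (nonnegative, sums to 1).
#' @param efficacies Numeric efficacy vector of the same length.
#' @return Scalar in `[-1, 1]`.
#' @export
synaptic_signal <- function(occupancy, efficacies) {
  if (length(occupancy) != length(efficacies)) {
    stop("occupancy and efficacies lengths differ", call. = FALSE)
  }
  sum(occupancy * efficacies)
}

steady_signal <- function(model, p_r) {
  synaptic_signal(steady_state(model, p_r), model$efficacies)
}

#' One-step noise at steady state
#'
#' The expected absolute change of the signal caused by a single
#' potentiation or depression event applied at the steady state:
#' `p_r * |S - S_pot| + (1 - p_r) * |S - S_dep|`. It measures the noise
#' generated in a single trial and is a lower bound on the noise observed
#' in stochastic simulations.
#'
#' @inheritParams average_transition
#' @return Nonnegative scalar.
#' @export
one_step_noise <- function(model, p_r) {
  psi <- steady_state(model, p_r)
  e <- model$efficacies
  s <- synaptic_signal(psi, e)
  s_pot <- synaptic_signal(drop(model$potentiation %*% psi), e)
  s_dep <- synaptic_signal(drop(model$depression %*% psi), e)
  p_r * abs(s - s_pot) + (1 - p_r) * abs(s - s_dep)
}

#' Sensitivity of the steady-state signal to reward probability
#'
#' Central finite difference of the steady-state signal with respect to
#' `p_r` (default step 0.005). Near the boundaries of `[0, 1]` a one-sided
#' difference is used and flagged via the `"one_sided"` attribute.
#'
#' @inheritParams average_transition
#' @param step Finite-difference step (default 0.005).
#' @return Scalar derivative `dS/dp_r`, with attribute `one_sided`.
#' @export
sensitivity <- function(model, p_r, step = 0.005) {
  check_p_r(p_r)
  lo <- p_r - step
  hi <- p_r + step
  one_sided <- FALSE
  if (lo < 0) {
    lo <- p_r
    one_sided <- TRUE
  }
  if (hi > 1) {
    hi <- p_r
    one_sided <- TRUE
  }
  if (hi <= lo) stop("step too large for interior difference", call. = FALSE)
  d <- (steady_signal(model, hi) - steady_signal(model, lo)) / (hi - lo)
  attr(d, "one_sided") <- one_sided
  d
}

#' Precision of the reward-probability estimate
#'
#' Ratio of sensitivity to one-step noise: how well the steady-state signal
#' discriminates between adjacent reward probabilities given the noise a
#' single update generates. Zero noise is signalled as degenerate.
#'
#' @inheritParams sensitivity
#' @return Nonnegative scalar.
#' @export
estimation_precision <- function(model, p_r, step = 0.005) {
  eta <- one_step_noise(model, p_r)
  if (eta <= 0) {
    stop("one-step noise is zero: precision is infinite (degenerate model)",
         call. = FALSE)
  }
  as.numeric(sensitivity(model, p_r, step)) / eta
}

#' Adaptability (spectral gap) of the averaged chain
#'
#' One minus the modulus of the second-largest-modulus eigenvalue of the
#' averaged transition matrix. The modulus of the subdominant eigenvalue
#' governs the asymptotic per-trial decay toward the steady state, so the
#' spectral gap lower-bounds the rate at which the signal converges after a
#' change in reward probability.
#'
#' @inheritParams average_transition
#' @return Scalar in `[0, 1]`.
#' @export
adaptability <- function(model, p_r) {
  m <- average_transition(model, p_r)
  mods <- sorted_eigen_moduli(m)
  if (sum(mods > 1 - .unit_gap_tol) != 1) {
    stop("non-unique steady state: spectral gap undefined", call. = FALSE)
  }
  1 - mods[2]
}

weak_idx <- function(model) seq_len(model$n_states / 2)
strong_idx <- function(model) (model$n_states / 2 + 1):model$n_states

#' Effective learning rates at steady state
#'
#' Summarizes all boundary-crossing (plastic) flow of a metaplastic model
#' by the single pair of rates a binary model would need: applying one
#' potentiation event to the steady state moves a fraction
#' `t_pot_eff * Psi_weak` of synapses into the strong side, and mirrored
#' for depression.
#'
#' @inheritParams average_transition
#' @return Named numeric vector `c(pot = t_pot_eff, dep = t_dep_eff)`.
#' @export
effective_learning_rates <- function(model, p_r) {
  psi <- steady_state(model, p_r)
  w <- weak_idx(model)
  s <- strong_idx(model)
  psi_w <- sum(psi[w])
  psi_s <- sum(psi[s])
  if (psi_w <= 0 || psi_s <= 0) {
    stop("effective learning rate undefined: one efficacy class is empty",
         call. = FALSE)
  }
  after_pot <- drop(model$potentiation %*% psi)
  after_dep <- drop(model$depression %*% psi)
  c(pot = (sum(after_pot[s]) - psi_s) / psi_w,
    dep = (sum(after_dep[w]) - psi_w) / psi_s)
}

#' Equivalent binary plastic model at a reward probability
#'
#' The binary model whose potentiation and depression rates equal the
#' metaplastic model's effective learning rates at `p_r`. Comparing the two
#' shows what the metaplastic structure adds beyond its average plastic
#' flow.
#'
#' @inheritParams average_transition
#' @return A `metaplastic_model` with `n_states = 2`.
#' @export
equivalent_binary_model <- function(model, p_r) {
  tr <- effective_learning_rates(model, p_r)
  build_binary_model(min(tr[["pot"]], 1), min(tr[["dep"]], 1))
}

#' Effective transition rates and conductance of all meta-state subsets
#'
#' For every proper nonempty subset of meta-states, computes the
#' steady-state occupancy mass, the effective transition rate (outward
#' probability flow divided by the subset's occupancy), and the Markov-chain
#' conductance (outward flow divided by the smaller of the subset and
#' complement occupancies). The subset with the smallest effective rate is
#' the flow bottleneck that constrains the spectral gap; in superior models
#' it separates weak from strong states.
#'
#' @inheritParams average_transition
#' @return Data frame with one row per subset: `subset` (comma-separated
#'   state indices), `size`, `occupancy_mass`, `eff_rate`, `conductance`,
#'   and `separates_boundary` (whether the shallowest weak and shallowest
#'   strong states fall on opposite sides of the cut). Attributes
#'   `bottleneck` and `fastest` give the rows with extreme effective rates.
#' @export
subset_flows <- function(model, p_r) {
  n <- model$n_states
  if (n > 12) {
    stop("subset enumeration limited to n_states <= 12; sample subsets ",
         "instead for larger models", call. = FALSE)
  }
  psi <- steady_state(model, p_r)
  m <- average_transition(model, p_r)
  half <- n / 2
  masks <- seq_len(2^n - 2)
  rows <- lapply(masks, function(b) {
    inS <- as.logical(bitwAnd(b, bitwShiftL(1L, 0:(n - 1L))))
    pi_s <- sum(psi[inS])
    flow <- sum(m[!inS, inS, drop = FALSE] %*% psi[inS])
    data.frame(
      subset = paste(which(inS), collapse = ","),
      size = sum(inS),
      occupancy_mass = pi_s,
      eff_rate = if (pi_s > 0) flow / pi_s else NA_real_,
      conductance = if (min(pi_s, 1 - pi_s) > 0)
        flow / min(pi_s, 1 - pi_s) else NA_real_,
      separates_boundary = xor(inS[half], inS[half + 1L])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bottleneck") <- out[which.min(out$eff_rate), ]
  attr(out, "fastest") <- out[which.max(out$eff_rate), ]
  out
}

#' Default reward-probability grid for averaged quantities
#'
#' 0.05 to 0.95 in steps of 0.05 (19 points); the endpoints 0 and 1 are
#' excluded because absorbing topologies make the steady state non-unique
#' there.
#'
#' @return Numeric vector of reward probabilities.
#' @export
default_p_r_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Mean-field summary over a reward-probability grid
#'
#' Evaluates signal, sensitivity, one-step noise, precision, adaptability
#' and effective learning rates at every grid point, and averages
#' adaptability and precision across the grid (the quantities whose product
#' the frontier optimizer maximizes). Grid points with a degenerate steady
#' state are skipped and reported in the `"skipped"` attribute.
#'
#' @param model A `metaplastic_model`.
#' @param p_r_grid Reward probabilities strictly inside `(0, 1)`.
#' @param step Finite-difference step for the sensitivity.
#' @return Data frame with one row per grid point and attribute
#'   `averages = list(avg_adaptability, avg_precision, objective)`.
#' @export
mf_summary <- function(model, p_r_grid = default_p_r_grid(), step = 0.005) {
  if (any(p_r_grid <= 0 | p_r_grid >= 1)) {
    stop("p_r_grid must lie strictly inside (0, 1)", call. = FALSE)
  }
  rows <- list()
  skipped <- numeric(0)
  for (p in p_r_grid) {
    row <- tryCatch({
      sens <- as.numeric(sensitivity(model, p, step))
      eta <- one_step_noise(model, p)
      tr <- effective_learning_rates(model, p)
      data.frame(
        p_r = p,
        signal = steady_signal(model, p),
        sensitivity = sens,
        one_step_noise = eta,
        precision = if (eta > 0) sens / eta else NA_real_,
        adaptability = adaptability(model, p),
        eff_rate_pot = tr[["pot"]],
        eff_rate_dep = tr[["dep"]]
      )
    }, error = function(e) NULL)
    if (is.null(row)) skipped <- c(skipped, p) else rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  avg_a <- mean(out$adaptability)
  avg_p <- mean(out$precision)
  attr(out, "averages") <- list(avg_adaptability = avg_a,
                                avg_precision = avg_p,
                                objective = avg_a * avg_p)
  attr(out, "skipped") <- skipped
  out
}

# Average adaptability/precision pair used by the frontier modules.
mf_averages <- function(model, p_r_grid = default_p_r_grid(), step = 0.005) {
  attr(mf_summary(model, p_r_grid, step), "averages")
}
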