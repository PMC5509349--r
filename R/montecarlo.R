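# Largest-remainder rounding of a fractional occupancy into integer counts.
occupancy_to_counts <- function(occupancy, n_synapses) {
  raw <- occupancy * n_synapses
  counts <- floor(raw)
  short <- n_synapses - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# One stochastic update of an ensemble of populations.  `counts` is an
# n_states x n_instances integer matrix; column j of `m` gives the
# destination distribution for synapses in state j.  The multinomial draw
# per (state, instance) is decomposed into sequential binomials so the
# instance dimension stays vectorized.
mc_step_counts <- function(counts, m) {
  n <- nrow(m)
  out <- matrix(0L, n, ncol(counts))
  for (i in seq_len(n)) {
    ni <- counts[i, ]
    if (all(ni == 0L)) next
    dests <- which(m[, i] > 0)
    remaining <- ni
    mass <- 1
    for (k in seq_along(dests)) {
      j <- dests[k]
      if (k == length(dests)) {
        x <- remaining
      } else {
        x <- stats::rbinom(length(ni), remaining, min(m[j, i] / mass, 1))
        remaining <- remaining - x
        mass <- mass - m[j, i]
      }
      out[j, ] <- out[j, ] + x
    }
  }
  out
}

resolve_p_path <- function(schedule) {
  if (inherits(schedule, "reward_schedule")) schedule$p_path
  else as.numeric(schedule)
}

#' Simulate a finite population of metaplastic synapses
#'
#' Trial-by-trial Monte Carlo simulation: each trial draws a reward outcome
#' from the scheduled probability, then every synapse independently
#' transitions according to the corresponding column of the potentiation or
#' depression matrix. The per-trial signal is the efficacy-weighted state
#' fraction.
#'
#' @param model A `metaplastic_model`.
#' @param schedule A [reward schedule][make_environment] or numeric vector
#'   of per-trial reward probabilities.
#' @param n_synapses Number of synapses in the population.
#' @param seed Integer seed (required for reproducibility).
#' @param init Initial occupancy fractions, or integer counts summing to
#'   `n_synapses`. Default: uniform.
#' @return Object of class `simulation_trace` with elements `rewards`,
#'   `signal_path`, `occupancy_path` (`n_states x n_trials` counts),
#'   `n_synapses`, `seed`.
#' @export
simulate_population <- function(model, schedule, n_synapses = 1000,
                                seed = 1, init = NULL) {
  p_path <- resolve_p_path(schedule)
  if (length(p_path) < 1) stop("schedule is empty", call. = FALSE)
  if (n_synapses < 1) stop("n_synapses must be >= 1", call. = FALSE)
  n <- model$n_states
  if (is.null(init)) {
    counts <- occupancy_to_counts(rep(1 / n, n), n_synapses)
  } else if (all(init == round(init)) && sum(init) == n_synapses &&
             length(init) == n) {
    counts <- as.integer(init)
  } else if (length(init) == n && abs(sum(init) - 1) < 1e-9 &&
             all(init >= 0)) {
    counts <- occupancy_to_counts(init, n_synapses)
  } else {
    stop("init must be occupancy fractions or counts summing to n_synapses",
         call. = FALSE)
  }
  set.seed(seed)
  n_trials <- length(p_path)
  rewards <- logical(n_trials)
  signal_path <- numeric(n_trials)
  occupancy_path <- matrix(0L, n, n_trials)
  cm <- matrix(counts, n, 1)
  for (t in seq_len(n_trials)) {
    r <- stats::runif(1) < p_path[t]
    m <- if (r) model$potentiation else model$depression
    cm <- mc_step_counts(cm, m)
    rewards[t] <- r
    occupancy_path[, t] <- cm[, 1]
    signal_path[t] <- sum(cm[, 1] * model$efficacies) / n_synapses
  }
  structure(
    list(rewards = rewards, signal_path = signal_path,
         occupancy_path = occupancy_path, n_synapses = n_synapses,
         seed = seed),
    class = "simulation_trace"
  )
}

# Advance a whole ensemble for `n_trials` trials at fixed reward
# probability; returns the final counts matrix and (optionally) the
# ensemble-mean signal path.
run_ensemble <- function(model, p_r, counts, n_trials, keep_mean = FALSE) {
  n_inst <- ncol(counts)
  eff <- model$efficacies
  n_syn <- sum(counts[, 1])
  mean_signal <- if (keep_mean) numeric(n_trials) else NULL
  for (t in seq_len(n_trials)) {
    rewarded <- stats::runif(n_inst) < p_r
    if (any(rewarded)) {
      counts[, rewarded] <- mc_step_counts(
        counts[, rewarded, drop = FALSE], model$potentiation)
    }
    if (any(!rewarded)) {
      counts[, !rewarded] <- mc_step_counts(
        counts[, !rewarded, drop = FALSE], model$depression)
    }
    if (keep_mean) {
      mean_signal[t] <- mean(crossprod(eff, counts)) / n_syn
    }
  }
  list(counts = counts, mean_signal = mean_signal)
}

ensemble_init <- function(model, p_r, n_synapses, n_instances) {
  counts <- occupancy_to_counts(steady_state(model, p_r), n_synapses)
  matrix(counts, model$n_states, n_instances)
}

#' Ensemble noise of the simulated signal
#'
#' Runs many independent populations at a fixed reward probability,
#' starting from the mean-field steady state, and returns the
#' across-instance standard deviation of the signal at the final trial
#' after a burn-in. This total noise always exceeds the one-step noise,
#' which only counts the fluctuation generated in a single trial.
#'
#' @param model A `metaplastic_model`.
#' @param p_r Fixed reward probability.
#' @param n_synapses Synapses per population.
#' @param n_instances Number of independent populations (at least 10).
#' @param burn_in Trials to discard before measuring.
#' @param seed Integer seed.
#' @return Scalar standard deviation, with attribute `se` (a jackknife-free
#'   standard error of the SD estimate from splitting the ensemble).
#' @export
measure_mc_noise <- function(model, p_r, n_synapses = 1000,
                             n_instances = 10000, burn_in = 500, seed = 1) {
  if (n_instances < 10) stop("need at least 10 instances", call. = FALSE)
  set.seed(seed)
  counts <- ensemble_init(model, p_r, n_synapses, n_instances)
  counts <- run_ensemble(model, p_r, counts, burn_in + 1)$counts
  signals <- as.numeric(crossprod(model$efficacies, counts)) / n_synapses
  est <- stats::sd(signals)
  groups <- rep(seq_len(10), length.out = n_instances)
  per_group <- tapply(signals, groups, stats::sd)
  attr(est, "se") <- stats::sd(per_group) / sqrt(length(per_group))
  est
}

#' Convergence rate of the ensemble-mean signal after a probability jump
#'
#' Equilibrates the ensemble at `p_from` (mean-field steady state), jumps
#' the reward probability to `p_to`, and fits an exponential to the
#' asymptotic approach of the ensemble-mean signal toward its new
#' mean-field value. The fitted time constant is reported as a per-trial
#' adaptability `1 - exp(-1/tau)`, commensurate with the spectral gap.
#'
#' @param model A `metaplastic_model`.
#' @param p_from,p_to Reward probabilities before and after the jump.
#' @param n_instances Number of independent populations.
#' @param n_synapses Synapses per population.
#' @param seed Integer seed.
#' @param n_trials Trials simulated after the jump; default scales with the
#'   mean-field relaxation time.
#' @param fit_window Fraction of the initial signal gap within which trials
#'   enter the fit (asymptotic but above the noise floor); default
#'   `c(0.02, 0.5)`.
#' @return List with `tau`, `mc_adaptability` (mean of 10 sub-ensemble
#'   fits), `mf_adaptability` (the same exponential fit applied to the
#'   exact mean-field trajectory — the comparable reference),
#'   `spectral_gap` (`1 - |lambda_2|` of the averaged matrix at `p_to`),
#'   `se` (standard error across sub-ensembles), `mean_signal`, `window`.
#' @export
measure_decay_rate <- function(model, p_from = 0.3, p_to = 0.8,
                               n_instances = 10000, n_synapses = 1000,
                               seed = 1, n_trials = NULL,
                               fit_window = c(0.02, 0.5)) {
  a_mf <- adaptability(model, p_to)
  if (is.null(n_trials)) {
    n_trials <- max(50, min(3000, ceiling(8 / max(a_mf, 1e-3))))
  }
  if (n_trials < 2) stop("post-jump window too short to fit", call. = FALSE)
  set.seed(seed)
  counts <- ensemble_init(model, p_from, n_synapses, n_instances)
  eff <- model$efficacies
  s_inf <- steady_signal(model, p_to)
  n_inst <- ncol(counts)
  groups <- rep(seq_len(10), length.out = n_inst)
  group_n <- tabulate(groups, 10)
  # per-trial signal means within 10 sub-ensembles (memory stays bounded)
  group_signal <- matrix(0, n_trials, 10)
  for (t in seq_len(n_trials)) {
    rewarded <- stats::runif(n_inst) < p_to
    if (any(rewarded)) {
      counts[, rewarded] <- mc_step_counts(
        counts[, rewarded, drop = FALSE], model$potentiation)
    }
    if (any(!rewarded)) {
      counts[, !rewarded] <- mc_step_counts(
        counts[, !rewarded, drop = FALSE], model$depression)
    }
    s_t <- as.numeric(crossprod(eff, counts)) / n_synapses
    group_signal[t, ] <- vapply(seq_len(10), function(g) {
      mean(s_t[groups == g])
    }, numeric(1))
  }
  # The fit window is fixed from the exact mean-field trajectory (the
  # expectation of every simulated path), so window selection adds no
  # noise; the exponential is fitted by least squares in signal space
  # (profile over the decay factor), which is unbiased under the additive
  # fluctuations of the ensemble mean.
  psi_mf <- steady_state(model, p_from)
  tbar <- average_transition(model, p_to)
  mf_gap <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    psi_mf <- drop(tbar %*% psi_mf)
    mf_gap[t] <- sum(psi_mf * eff) - s_inf
  }
  rel <- abs(mf_gap) / abs(mf_gap[1])
  keep <- which(rel <= fit_window[2] & rel >= fit_window[1])
  if (length(keep) < 3) {
    stop("post-jump fit window too short (", length(keep), " usable trials);",
         " increase n_trials or widen fit_window", call. = FALSE)
  }
  fit_rate <- function(s_path) {
    gap <- s_path[keep] - s_inf
    sse <- function(lam) {
      basis <- lam^keep
      b <- sum(gap * basis) / sum(basis^2)
      sum((gap - b * basis)^2)
    }
    opt <- stats::optimize(sse, c(0.2, 0.99999), tol = 1e-9)
    lam <- opt$minimum
    if (lam >= 0.99999 - 1e-8) return(NA_real_)
    1 - lam                            # per-trial adaptability 1 - lambda
  }
  mean_signal <- as.numeric(group_signal %*% group_n) / n_inst
  # batch-means estimator: the reported rate and its standard error come
  # from the same family of sub-ensemble fits, so they are commensurate
  sub <- vapply(seq_len(10), function(g) fit_rate(group_signal[, g]),
                numeric(1))
  sub <- sub[is.finite(sub)]
  if (length(sub) < 3) {
    stop("exponential fit did not converge; inspect the mean signal path ",
         "(initial gap ", signif(mean_signal[1] - s_inf, 3), ", final gap ",
         signif(mean_signal[n_trials] - s_inf, 3), ")", call. = FALSE)
  }
  a_mc <- mean(sub)
  se <- stats::sd(sub) / sqrt(length(sub))
  # comparable mean-field value: the same exponential fit applied to the
  # exact mean-field trajectory.  A single exponential fitted on a finite
  # window of a multi-mode relaxation is not exactly the spectral gap, so
  # comparing two identically-fitted rates isolates the Monte Carlo error;
  # the raw spectral gap is reported alongside.
  a_mf_fit <- fit_rate(mf_gap + s_inf)
  list(tau = -1 / log(1 - a_mc), mc_adaptability = a_mc,
       mf_adaptability = a_mf_fit, spectral_gap = a_mf, se = se,
       mean_signal = mean_signal, window = fit_window)
}
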