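#' Generate a dynamic reward-probability schedule
#'
#' The true reward probability starts at 0.5 and moves up or down by 0.1
#' (with equal probability) every `L` trials, staying on the lattice
#' `{0, 0.1, ..., 1}` (11 levels); at the boundaries the step is reflected
#' inward. Passing a vector of `L` values produces the complex environment:
#' after each probability change a block length is drawn from the set,
#' preferring the value with the smallest total trial count so far, so that
#' overall exposure to every volatility level stays balanced.
#'
#' @param L Block length (scalar) or set of block lengths (vector).
#' @param n_trials Total number of trials.
#' @param seed Integer seed.
#' @return Object of class `reward_schedule`: `p_path`, `block_lengths`,
#'   `L`, `seed`.
#' @export
make_environment <- function(L, n_trials, seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (any(L < 1 | L != round(L))) {
    stop("L must contain positive integers", call. = FALSE)
  }
  set.seed(seed)
  level <- 5L                       # tenths: start at p = 0.5
  p_path <- numeric(n_trials)
  block_lengths <- integer(0)
  totals <- stats::setNames(rep(0L, length(L)), L)
  t <- 1L
  while (t <= n_trials) {
    if (length(L) == 1L) {
      len <- L
    } else {
      least <- which(totals == min(totals))
      pick <- if (length(least) > 1) sample(least, 1) else least
      len <- L[pick]
      totals[pick] <- totals[pick] + len
    }
    len_used <- min(len, n_trials - t + 1L)
    p_path[t:(t + len_used - 1L)] <- level / 10
    block_lengths <- c(block_lengths, len_used)
    t <- t + len_used
    step <- if (level == 0L) 1L else if (level == 10L) -1L else
      sample(c(-1L, 1L), 1)
    level <- level + step
  }
  structure(list(p_path = p_path, block_lengths = block_lengths, L = L,
                 seed = seed),
            class = "reward_schedule")
}

#' Learner constructors for the probability-estimation benchmark
#'
#' `learner_synaptic()` wraps any `metaplastic_model` as a deterministic
#' infinite-population learner: on each trial the occupancy is multiplied
#' by the potentiation (rewarded) or depression (unrewarded) matrix and the
#' probability estimate is `(signal + 1) / 2`. `learner_delta()` is the
#' delta-rule (reinforcement learning) estimator `V <- V + alpha (r - V)`.
#' `learner_bayesian()` is a hierarchical grid filter over reward
#' probability, volatility, and a volatility-scale hyperparameter (a
#' reconstruction of volatility-tracking Bayesian learners; all grid sizes
#' are configurable).
#'
#' @param model A `metaplastic_model`.
#' @param name Optional display name (defaults to the model family).
#' @return An object of class `learner`.
#' @export
learner_synaptic <- function(model, name = NULL) {
  structure(list(type = "synaptic", model = model,
                 name = name %||% model$family),
            class = "learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname learner_synaptic
#' @param alpha Learning rate in `[0, 1]`.
#' @export
learner_delta <- function(alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  structure(list(type = "delta", alpha = alpha, name = "delta-rule"),
            class = "learner")
}

#' @rdname learner_synaptic
#' @param n_p,n_v,n_k Grid sizes for probability, volatility, and the
#'   volatility-scale hyperparameter (defaults 50, 30, 15).
#' @param v_range,k_range Ranges of the log-spaced volatility and
#'   volatility-scale grids.
#' @export
learner_bayesian <- function(n_p = 50, n_v = 30, n_k = 15,
                             v_range = c(1e-4, 1), k_range = c(0.01, 1)) {
  p_grid <- (seq_len(n_p) - 0.5) / n_p
  v_grid <- exp(seq(log(v_range[1]), log(v_range[2]), length.out = n_v))
  k_grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  # probability transition per volatility level: Beta kernel with mean at
  # the previous probability and concentration 1/v
  p_trans <- lapply(v_grid, function(v) {
    s <- 1 / v
    m <- vapply(p_grid, function(mu) {
      a <- mu * s
      b <- (1 - mu) * s
      d <- stats::dbeta(p_grid, a, b)
      if (sum(d) <= 0 || !all(is.finite(d))) {
        d <- as.numeric(seq_along(p_grid) == which.min(abs(p_grid - mu)))
      }
      d / sum(d)
    }, numeric(n_p))
    m                                    # column = old p, row = new p
  })
  # volatility log random walk with sd k
  v_trans <- lapply(k_grid, function(k) {
    lv <- log(v_grid)
    m <- vapply(lv, function(mu) {
      d <- stats::dnorm(lv, mu, k)
      d / sum(d)
    }, numeric(n_v))
    m
  })
  structure(list(type = "bayesian", name = "bayesian", p_grid = p_grid,
                 v_grid = v_grid, k_grid = k_grid, p_trans = p_trans,
                 v_trans = v_trans),
            class = "learner")
}

run_bayesian <- function(learner, rewards) {
  n_p <- length(learner$p_grid)
  n_v <- length(learner$v_grid)
  n_k <- length(learner$k_grid)
  joint <- array(1 / (n_p * n_v * n_k), c(n_p, n_v, n_k))
  est <- numeric(length(rewards))
  for (t in seq_along(rewards)) {
    # volatility diffusion (per hyperparameter level)
    for (k in seq_len(n_k)) {
      joint[, , k] <- joint[, , k] %*% t(learner$v_trans[[k]])
    }
    # probability diffusion (per volatility level)
    for (v in seq_len(n_v)) {
      joint[, v, ] <- learner$p_trans[[v]] %*% joint[, v, ]
    }
    lik <- if (rewards[t]) learner$p_grid else 1 - learner$p_grid
    joint <- joint * lik
    joint <- joint / sum(joint)
    est[t] <- sum(learner$p_grid * apply(joint, 1, sum))
  }
  est
}

#' Run a learner on a reward schedule
#'
#' Draws the per-trial reward outcomes from the schedule's true
#' probabilities (the same seed gives the same reward sequence for every
#' learner) and then updates the learner deterministically. Estimates are
#' reported on the probability scale (`(signal + 1) / 2` for synaptic
#' learners).
#'
#' @param learner A [learner][learner_synaptic].
#' @param schedule A `reward_schedule`.
#' @param seed Integer seed used for the reward draws.
#' @return Object of class `estimate_trace`: `estimate` (per-trial
#'   probability estimate), `rewards`, `learner`.
#' @export
run_learner <- function(learner, schedule, seed = 1) {
  if (!inherits(learner, "learner")) stop("unknown learner", call. = FALSE)
  p_path <- resolve_p_path(schedule)
  set.seed(seed)
  rewards <- stats::runif(length(p_path)) < p_path
  est <- switch(
    learner$type,
    synaptic = {
      model <- learner$model
      psi <- rep(1 / model$n_states, model$n_states)
      out <- numeric(length(rewards))
      for (t in seq_along(rewards)) {
        m <- if (rewards[t]) model$potentiation else model$depression
        psi <- drop(m %*% psi)
        out[t] <- (synaptic_signal(psi, model$efficacies) + 1) / 2
      }
      out
    },
    delta = {
      v <- 0.5
      out <- numeric(length(rewards))
      for (t in seq_along(rewards)) {
        v <- v + learner$alpha * (rewards[t] - v)
        out[t] <- v
      }
      out
    },
    bayesian = run_bayesian(learner, rewards),
    stop("unknown learner type: ", learner$type, call. = FALSE)
  )
  structure(list(estimate = est, rewards = rewards, learner = learner,
                 seed = seed),
            class = "estimate_trace")
}

# Steady-state probability estimate per lattice level for a learner.
steady_estimate_map <- function(learner, levels) {
  if (learner$type != "synaptic") {
    return(stats::setNames(levels, sprintf("%.1f", levels)))
  }
  model <- learner$model
  vals <- vapply(levels, function(p) {
    p_in <- p
    tryCatch(
      (steady_signal(model, p_in) + 1) / 2,
      error = function(e) {
        # absorbing boundary: one-sided limit
        p_in <- min(max(p_in, 1e-6), 1 - 1e-6)
        (steady_signal(model, p_in) + 1) / 2
      })
  }, numeric(1))
  stats::setNames(vals, sprintf("%.1f", levels))
}

#' Relative estimation error of a trace
#'
#' Mean absolute difference between the trace's estimate and the learner's
#' own steady-state estimate at the true reward probability of each trial.
#' This scores how quickly the learner reaches the value it would settle
#' on, irrespective of any bias of that settled value.
#'
#' @param trace An `estimate_trace`.
#' @param schedule The `reward_schedule` it was run on.
#' @return Nonnegative scalar.
#' @export
relative_error <- function(trace, schedule) {
  p_path <- resolve_p_path(schedule)
  levels <- sort(unique(p_path))
  map <- steady_estimate_map(trace$learner, levels)
  target <- map[sprintf("%.1f", p_path)]
  mean(abs(trace$estimate - target))
}

#' Absolute estimation error of a trace
#'
#' Mean absolute difference between the estimated and true reward
#' probability per trial.
#'
#' @inheritParams relative_error
#' @return Nonnegative scalar.
#' @export
absolute_error <- function(trace, schedule) {
  p_path <- resolve_p_path(schedule)
  mean(abs(trace$estimate - p_path))
}

#' Benchmark learners across parameter grids and environments
#'
#' For each environment replicate, generates a fresh schedule, runs every
#' learner configuration on the same reward sequence, and records both
#' error measures. Results are averaged over replicates with Monte Carlo
#' standard errors.
#'
#' @param specs Named list; each element is a list with `make` (a function
#'   of one parameter returning a [learner][learner_synaptic]) and `grid`
#'   (parameter values, or `NULL` for parameter-free learners whose `make`
#'   takes no argument).
#' @param environments Named list; each element a list with `L` and
#'   `n_trials`.
#' @param n_reps Number of schedule replicates per environment.
#' @param seed Integer master seed.
#' @return Tidy data frame: `learner`, `parameter`, `environment`,
#'   `metric` (`"relative"` or `"absolute"`), `mean`, `sem`.
#' @export
benchmark_learners <- function(specs, environments, n_reps = 10, seed = 1) {
  rows <- list()
  for (e in seq_along(environments)) {
    env <- environments[[e]]
    env_name <- names(environments)[e]
    for (rep in seq_len(n_reps)) {
      run_seed <- seed + 7919L * e + rep
      schedule <- make_environment(env$L, env$n_trials, seed = run_seed)
      for (l in seq_along(specs)) {
        spec <- specs[[l]]
        grid <- spec$grid %||% NA_real_
        for (par in grid) {
          learner <- if (is.na(par)) spec$make() else spec$make(par)
          trace <- run_learner(learner, schedule, seed = run_seed)
          rows[[length(rows) + 1]] <- data.frame(
            learner = names(specs)[l], parameter = par,
            environment = env_name, rep = rep,
            relative = relative_error(trace, schedule),
            absolute = absolute_error(trace, schedule))
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  # NA parameters (parameter-free learners) must survive the grouping
  key <- paste(long$learner, long$parameter, long$environment, sep = "\r")
  agg <- do.call(rbind, lapply(
    split(long, key),
    function(d) {
      data.frame(
        learner = d$learner[1], parameter = d$parameter[1],
        environment = d$environment[1],
        metric = c("relative", "absolute"),
        mean = c(mean(d$relative), mean(d$absolute)),
        sem = c(stats::sd(d$relative), stats::sd(d$absolute)) /
          sqrt(nrow(d)))
    }))
  rownames(agg) <- NULL
  agg
}
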