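# Batch mean-field averages for parameter matrices of the symmetric
# family, via the compiled core.  Rows that are infeasible or degenerate
# come back as NA.
batch_averages <- function(params, n_states, p_r_grid = default_p_r_grid(),
                           step = 0.005) {
  if (!is.matrix(params)) params <- matrix(params, nrow = 1)
  out <- mf_batch_cpp(params, as.integer(n_states), p_r_grid, step)
  colnames(out) <- c("avg_adaptability", "avg_precision")
  out
}

# Rejection sampler: independent uniforms per free rate, resampled until
# every source state's outflow is at most 1.
sample_valid_params <- function(n_samples, n_states, max_tries = 10000) {
  k <- n_unique_rates(n_states)
  idx <- rate_index(n_states)
  src <- idx$source
  out <- matrix(NA_real_, n_samples, k)
  need <- seq_len(n_samples)
  tries <- 0
  while (length(need) > 0 && tries < max_tries) {
    tries <- tries + 1
    draw <- matrix(stats::runif(length(need) * k), length(need), k)
    src_ind <- outer(src, seq_len(max(src)), "==") + 0
    outflow <- draw %*% src_ind
    ok <- rowSums(outflow > 1) == 0
    if (any(ok)) {
      take <- need[ok]
      out[take, ] <- draw[ok, , drop = FALSE]
      need <- need[!ok]
    }
  }
  if (length(need) > 0) stop("parameter rejection sampling did not finish")
  out
}

#' Stage one of frontier discovery: random sampling
#'
#' Draws random valid parameter vectors of the symmetric family, scores
#' each by its grid-averaged adaptability and precision, bins the samples
#' by average precision, and keeps the sample with the largest objective
#' (average adaptability times average precision) in each bin. The kept
#' models outline the empirical adaptability-precision frontier.
#'
#' @param n_states Even integer, number of meta-states.
#' @param n_samples Number of random models to draw.
#' @param n_bins Number of equal-width precision bins over the observed
#'   range (default 20).
#' @param seed Integer seed.
#' @param p_r_grid Reward probabilities averaged over.
#' @return Data frame of class `frontier` with one row per nonempty bin:
#'   `bin_index`, `bin_center`, `avg_precision`, `avg_adaptability`,
#'   `objective`, and a `params` list-column. Attributes: `n_states`,
#'   `p_r_grid`, `bin_edges`, `empty_bins`.
#' @export
random_frontier <- function(n_states, n_samples, n_bins = 20, seed = 1,
                            p_r_grid = default_p_r_grid()) {
  if (n_samples < n_bins) stop("n_samples must be >= n_bins", call. = FALSE)
  set.seed(seed)
  params <- sample_valid_params(n_samples, n_states)
  stats_mat <- batch_averages(params, n_states, p_r_grid)
  ok <- is.finite(stats_mat[, 1]) & is.finite(stats_mat[, 2]) &
    stats_mat[, "avg_precision"] > 0
  params <- params[ok, , drop = FALSE]
  stats_mat <- stats_mat[ok, , drop = FALSE]
  prec <- stats_mat[, "avg_precision"]
  edges <- seq(min(prec), max(prec), length.out = n_bins + 1)
  bin <- findInterval(prec, edges, rightmost.closed = TRUE, all.inside = TRUE)
  objective <- stats_mat[, "avg_adaptability"] * prec
  rows <- lapply(seq_len(n_bins), function(b) {
    members <- which(bin == b)
    if (length(members) == 0) return(NULL)
    best <- members[which.max(objective[members])]
    data.frame(bin_index = b,
               bin_center = (edges[b] + edges[b + 1]) / 2,
               avg_precision = prec[best],
               avg_adaptability = stats_mat[best, "avg_adaptability"],
               objective = objective[best])
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out$params <- lapply(which(keep), function(b) {
    members <- which(bin == b)
    params[members[which.max(objective[members])], ]
  })
  class(out) <- c("frontier", class(out))
  attr(out, "n_states") <- as.integer(n_states)
  attr(out, "p_r_grid") <- p_r_grid
  attr(out, "bin_edges") <- edges
  attr(out, "empty_bins") <- which(!keep)
  out
}

# Penalized objective used during local refinement: the raw objective
# minus a soft pull toward the bin's precision center (weight 1e-3 times
# the objective) and hard penalties for infeasible parameters.
refine_objective <- function(params, n_states, p_r_grid, bin_center,
                             bin_width, step = 0.005) {
  if (any(params < 0)) return(-1e6 * (1 + sum(pmax(-params, 0))))
  st <- batch_averages(matrix(params, nrow = 1), n_states, p_r_grid, step)
  a <- st[1, "avg_adaptability"]
  p <- st[1, "avg_precision"]
  if (!is.finite(a) || !is.finite(p)) return(-1e6)
  obj <- a * p
  obj - 1e-3 * abs(obj) * abs(p - bin_center) / bin_width
}

#' Stage two of frontier discovery: local refinement
#'
#' For each precision bin, runs derivative-free (Nelder-Mead) maximization
#' of the objective starting from the incumbent model and from a jittered
#' duplicate (multiplicative Gaussian jitter on nonzero rates), keeping
#' whichever result improves the raw objective. Infeasible parameter
#' vectors are handled by penalty; a soft penalty keeps each search near
#' its bin's precision center. The per-bin objective never decreases.
#'
#' @param frontier Output of [random_frontier()].
#' @param iterations Number of refinement rounds (each restarts
#'   Nelder-Mead from the current incumbent and a fresh jittered copy).
#' @param jitter_scale Standard deviation of the multiplicative jitter
#'   (default 0.05).
#' @param seed Integer seed.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `frontier` data frame of the same shape with improved rows.
#' @export
refine_frontier <- function(frontier, iterations = 3, jitter_scale = 0.05,
                            seed = 1, maxit = 400) {
  if (iterations == 0) return(frontier)
  n_states <- attr(frontier, "n_states")
  p_r_grid <- attr(frontier, "p_r_grid")
  edges <- attr(frontier, "bin_edges")
  bin_width <- diff(edges)[1]
  set.seed(seed)
  for (it in seq_len(iterations)) {
    for (r in seq_len(nrow(frontier))) {
      inc <- frontier$params[[r]]
      center <- frontier$bin_center[r]
      jit <- inc * (1 + jitter_scale * stats::rnorm(length(inc)))
      jit <- pmax(jit, 0)
      starts <- list(inc, jit)
      for (s0 in starts) {
        opt <- tryCatch(
          stats::optim(s0, function(p) {
            -refine_objective(p, n_states, p_r_grid, center, bin_width)
          }, method = "Nelder-Mead", control = list(maxit = maxit)),
          error = function(e) NULL)
        if (is.null(opt)) next
        cand <- pmax(opt$par, 0)
        st <- batch_averages(matrix(cand, nrow = 1), n_states, p_r_grid)
        a <- st[1, "avg_adaptability"]
        p <- st[1, "avg_precision"]
        if (!is.finite(a) || !is.finite(p)) next
        if (a * p > frontier$objective[r]) {
          frontier$params[[r]] <- cand
          frontier$objective[r] <- a * p
          frontier$avg_adaptability[r] <- a
          frontier$avg_precision[r] <- p
        }
      }
    }
  }
  frontier
}

#' Classify meta-states into reservoirs, buffers, and transients
#'
#' A meta-state is a *buffer* if it takes part in an above-tolerance
#' plastic (efficacy-changing) transition in either matrix; the deepest
#' weak and strong meta-states are *reservoirs* when they are not buffers
#' (they store signal while only undergoing metaplastic transitions);
#' remaining states are *transient*, routing synapses between reservoirs
#' and buffers.
#'
#' @param model A `metaplastic_model`.
#' @param tolerance Rates below `tolerance * max(rate)` count as zero
#'   (default 0.01).
#' @return Character vector of per-state labels
#'   (`"reservoir"`, `"buffer"`, or `"transient"`).
#' @export
classify_states <- function(model, tolerance = 0.01) {
  n <- model$n_states
  half <- n / 2
  eff_class <- rep(c(-1, 1), each = half)
  is_plastic <- outer(eff_class, eff_class, "!=")  # [dest, source] crossing
  thr <- tolerance * max(model$potentiation[lower.tri(model$potentiation)],
                         model$depression[upper.tri(model$depression)])
  involved <- rep(FALSE, n)
  for (m in list(model$potentiation, model$depression)) {
    off <- m
    diag(off) <- 0
    hit <- which(off > thr & is_plastic, arr.ind = TRUE)
    involved[unique(c(hit[, 1], hit[, 2]))] <- TRUE
  }
  labels <- ifelse(involved, "buffer", "transient")
  if (!involved[1]) labels[1] <- "reservoir"
  if (!involved[n]) labels[n] <- "reservoir"
  labels
}

#' Count near-zero free potentiation rates of a symmetric-family model
#'
#' Helper for inspecting refined frontier models: how many of the
#' `N(N-1)/2` unique potentiation rates fall below `tolerance` times the
#' largest rate.
#'
#' @param params Free-rate vector of the symmetric family.
#' @param tolerance Relative threshold (default 0.01).
#' @return Integer count.
#' @export
count_near_zero_rates <- function(params, tolerance = 0.01) {
  sum(params < tolerance * max(params))
}

#' Compare one-parameter families across numbers of meta-states
#'
#' Sweeps the single transition probability for each requested number of
#' meta-states and records the grid-averaged adaptability and precision.
#' When `matched_precision` values are supplied, the objective of every
#' family is linearly interpolated at those average-precision values so
#' families can be ordered at matched precision.
#'
#' @param n_states_list Integer vector of meta-state counts.
#' @param q_grid Transition probabilities swept (default 30 points in
#'   `[0.02, 0.98]`).
#' @param p_r_grid Reward probabilities averaged over.
#' @param matched_precision Optional numeric vector of average-precision
#'   values at which to interpolate the objective.
#' @return Data frame with `n_states`, `q`, `avg_adaptability`,
#'   `avg_precision`, `objective`; if `matched_precision` is given, the
#'   interpolated table is in the `"matched"` attribute (columns
#'   `n_states`, `avg_precision`, `objective`).
#' @export
frontier_comparison <- function(n_states_list,
                                q_grid = seq(0.02, 0.98, length.out = 30),
                                p_r_grid = default_p_r_grid(),
                                matched_precision = NULL) {
  if (length(n_states_list) == 0) {
    return(data.frame(n_states = integer(0), q = numeric(0),
                      avg_adaptability = numeric(0),
                      avg_precision = numeric(0), objective = numeric(0)))
  }
  rows <- lapply(n_states_list, function(n) {
    idx <- rate_index(n)
    params <- matrix(0, length(q_grid), n_unique_rates(n))
    params[, idx$dest == idx$source + 1L] <- q_grid
    st <- batch_averages(params, n, p_r_grid)
    data.frame(n_states = n, q = q_grid,
               avg_adaptability = as.numeric(st[, "avg_adaptability"]),
               avg_precision = as.numeric(st[, "avg_precision"]),
               objective = as.numeric(st[, "avg_adaptability"] *
                                        st[, "avg_precision"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(matched_precision)) {
    matched <- do.call(rbind, lapply(split(out, out$n_states), function(d) {
      d <- d[is.finite(d$avg_precision) & is.finite(d$objective), ]
      data.frame(
        n_states = d$n_states[1],
        avg_precision = matched_precision,
        objective = stats::approx(d$avg_precision, d$objective,
                                  xout = matched_precision, rule = 1)$y)
    }))
    rownames(matched) <- NULL
    attr(out, "matched") <- matched
  }
  out
}
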