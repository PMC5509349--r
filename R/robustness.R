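#' Randomly perturb a model's nonzero transition rates
#'
#' Multiplies every nonzero off-diagonal rate of both matrices
#' independently by `1 + fraction * z` with standard normal `z`, truncating
#' below at 1e-6 so rates stay positive, then recomputes the stay
#' probabilities. The zero pattern (transition topology) is preserved. If a
#' perturbed column's outflow exceeds 1, its off-diagonal entries are
#' rescaled proportionally and the column is flagged in the
#' `"rescaled_columns"` attribute.
#'
#' @param model A `metaplastic_model`.
#' @param fraction Perturbation magnitude (e.g. 0.1 for 10%).
#' @param seed Integer seed.
#' @return A perturbed `metaplastic_model` (family suffixed
#'   `"_perturbed"`).
#' @export
perturb_model <- function(model, fraction, seed = 1) {
  if (fraction < 0) stop("fraction must be >= 0", call. = FALSE)
  set.seed(seed)
  rescaled <- character(0)
  perturb_one <- function(m, nm) {
    n <- nrow(m)
    off <- m
    diag(off) <- 0
    nz <- which(off > 0)
    off[nz] <- pmax(off[nz] * (1 + fraction * stats::rnorm(length(nz))),
                    1e-6)
    outflow <- colSums(off)
    over <- which(outflow > 1)
    if (length(over) > 0) {
      off[, over] <- sweep(off[, over, drop = FALSE], 2, outflow[over], "/")
      rescaled <<- c(rescaled, paste0(nm, ":", over))
    }
    set_diagonal_remainder(off)
  }
  out <- model
  out$potentiation <- perturb_one(model$potentiation, "potentiation")
  out$depression <- perturb_one(model$depression, "depression")
  out$family <- paste0(model$family, "_perturbed")
  attr(out, "rescaled_columns") <- rescaled
  out
}

#' Perturbation robustness report
#'
#' Generates perturbed replicates of a model and records each replicate's
#' grid-averaged adaptability and precision, to quantify how robust the
#' model's position in the adaptability-precision plane is to jitter in its
#' transition rates.
#'
#' @param model A `metaplastic_model`.
#' @param fraction Perturbation magnitude.
#' @param n_replicates Number of perturbed replicates.
#' @param seed Integer seed.
#' @param p_r_grid Reward probabilities averaged over.
#' @return Data frame with one row per replicate (`avg_adaptability`,
#'   `avg_precision`, `objective`) plus the unperturbed model's row first
#'   (`replicate = 0`).
#' @export
perturbation_report <- function(model, fraction = 0.1, n_replicates = 100,
                                seed = 1, p_r_grid = default_p_r_grid()) {
  base <- mf_averages(model, p_r_grid)
  rows <- list(data.frame(replicate = 0, fraction = 0,
                          avg_adaptability = base$avg_adaptability,
                          avg_precision = base$avg_precision,
                          objective = base$objective))
  for (r in seq_len(n_replicates)) {
    pm <- perturb_model(model, fraction, seed = seed + r)
    av <- mf_averages(pm, p_r_grid)
    rows[[r + 1]] <- data.frame(replicate = r, fraction = fraction,
                                avg_adaptability = av$avg_adaptability,
                                avg_precision = av$avg_precision,
                                objective = av$objective)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep graded efficacies against the metaplastic corner
#'
#' Evaluates the grid-averaged adaptability-precision objective of graded
#' plastic models (ladder topology with intermediate efficacy magnitudes)
#' over a grid of transition rates and inner-state efficacies. The corner
#' with all magnitudes equal to 1 is the metaplastic model itself; the
#' sweep quantifies how replacing metaplastic transitions with graded
#' plastic ones degrades the objective.
#'
#' @param n_states 4 or 6 (one or two free efficacy magnitudes).
#' @param q_values Transition probabilities to sweep.
#' @param efficacy_grid Efficacy magnitudes in `(0, 1]` for the inner
#'   states; for `n_states = 6` all pairs `w1 >= w2` from this grid are
#'   used.
#' @param p_r_grid Reward probabilities averaged over.
#' @return Data frame: `q`, `w1` (and `w2` for six states),
#'   `avg_adaptability`, `avg_precision`, `objective`.
#' @export
graded_sweep <- function(n_states, q_values,
                         efficacy_grid = seq(0.1, 1, by = 0.1),
                         p_r_grid = default_p_r_grid()) {
  if (!n_states %in% c(4, 6)) {
    stop("graded sweep implemented for n_states 4 and 6", call. = FALSE)
  }
  if (any(efficacy_grid <= 0 | efficacy_grid > 1)) {
    stop("efficacy magnitudes must lie in (0, 1]", call. = FALSE)
  }
  if (n_states == 4) {
    cells <- expand.grid(q = q_values, w1 = efficacy_grid)
    cells$w2 <- NA_real_
  } else {
    cells <- expand.grid(q = q_values, w1 = efficacy_grid,
                         w2 = efficacy_grid)
    cells <- cells[cells$w1 >= cells$w2, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    q <- cells$q[i]
    eff <- if (n_states == 4) {
      c(-1, -cells$w1[i], cells$w1[i], 1)
    } else {
      c(-1, -cells$w1[i], -cells$w2[i], cells$w2[i], cells$w1[i], 1)
    }
    m <- build_graded_model(q, eff)
    av <- mf_averages(m, p_r_grid)
    data.frame(q = q, w1 = cells$w1[i], w2 = cells$w2[i],
               avg_adaptability = av$avg_adaptability,
               avg_precision = av$avg_precision,
               objective = av$objective)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_states == 4) out$w2 <- NULL
  out
}
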