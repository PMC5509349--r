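#' Number of unique transition probabilities of the symmetric family
#'
#' A mirror-symmetric metaplastic model with `n_states` ordered meta-states
#' has one free rate per directed potentiation transition `i -> j` with
#' `j > i`, i.e. `n_states * (n_states - 1) / 2` free parameters; the
#' depression matrix is fixed by the reflection symmetry and the stay
#' probabilities by probability conservation.
#'
#' @param n_states Even integer, number of meta-states.
#' @return Integer count of free transition probabilities.
#' @export
n_unique_rates <- function(n_states) {
  check_n_states(n_states)
  as.integer(n_states * (n_states - 1) / 2)
}

check_n_states <- function(n_states) {
  if (length(n_states) != 1 || n_states < 2 || n_states %% 2 != 0 ||
      n_states != round(n_states)) {
    stop("n_states must be a single even integer >= 2", call. = FALSE)
  }
  invisible(as.integer(n_states))
}

#' Index table for the free rates of the symmetric family
#'
#' Maps each entry of a [ModelParams] vector to its (source, destination)
#' pair in the potentiation matrix. The ordering is source-major:
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).
#'
#' @param n_states Even integer, number of meta-states.
#' @return Data frame with columns `source`, `dest`, `index`.
#' @export
rate_index <- function(n_states) {
  n <- check_n_states(n_states)
  src <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  dst <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  data.frame(source = src, dest = dst, index = seq_along(src))
}

default_efficacies <- function(n_states) {
  c(rep(-1, n_states / 2), rep(1, n_states / 2))
}

new_metaplastic_model <- function(n_states, potentiation, depression,
                                  efficacies, family, params) {
  structure(
    list(
      n_states = as.integer(n_states),
      potentiation = potentiation,
      depression = depression,
      efficacies = efficacies,
      family = family,
      params = params
    ),
    class = "metaplastic_model"
  )
}

# Fill stay probabilities so every source column sums to one.
set_diagonal_remainder <- function(m) {
  diag(m) <- 0
  diag(m) <- 1 - colSums(m)
  m
}

# Reflection of the state ladder: state i maps to N+1-i.  Applied to the
# potentiation matrix it produces the mirror-symmetric depression matrix.
reflect_matrix <- function(m) {
  n <- nrow(m)
  m[n:1, n:1, drop = FALSE]
}

#' Build a general mirror-symmetric metaplastic model
#'
#' Constructs the `N`-meta-state model from its free transition
#' probabilities. States are ordered by depth: index 1 is the deepest weak
#' state, `N/2` the shallowest weak, `N/2 + 1` the shallowest strong, and
#' `N` the deepest strong state. Potentiation (applied on rewarded trials)
#' only moves synapses toward the deep-strong end (destination index above
#' source index); depression is its mirror image under the reflection
#' `i -> N + 1 - i`. Stay probabilities are the diagonal remainder enforcing
#' probability conservation per source state.
#'
#' @param params Numeric vector of length `n_states * (n_states - 1) / 2`,
#'   the free potentiation rates in the order given by [rate_index()].
#' @param n_states Even integer, number of meta-states.
#' @return An object of class `metaplastic_model`.
#' @examples
#' m <- build_symmetric_model(c(0.1, 0, 0.05, 0.2, 0, 0.1), 4)
#' validate_model(m)
#' @export
build_symmetric_model <- function(params, n_states) {
  n <- check_n_states(n_states)
  k <- n_unique_rates(n)
  if (length(params) != k) {
    stop(sprintf("params must have length %d for n_states = %d", k, n),
         call. = FALSE)
  }
  if (any(params < 0)) {
    stop("negative transition rate at index ",
         paste(which(params < 0), collapse = ", "), call. = FALSE)
  }
  idx <- rate_index(n)
  pot <- matrix(0, n, n)
  pot[cbind(idx$dest, idx$source)] <- params
  outflow <- colSums(pot)
  bad <- which(outflow > 1 + 1e-12)
  if (length(bad) > 0) {
    stop("outflow from source state(s) ", paste(bad, collapse = ", "),
         " exceeds 1", call. = FALSE)
  }
  pot <- set_diagonal_remainder(pot)
  dep <- reflect_matrix(pot)
  new_metaplastic_model(n, pot, dep, default_efficacies(n),
                        "symmetric", params)
}

#' Build a binary plastic model (two states, possibly asymmetric rates)
#'
#' The classic binary stochastic synapse: weak synapses potentiate with
#' probability `t_pot` on rewarded trials, strong synapses depress with
#' probability `t_dep` on unrewarded trials. Equivalent to a delta-rule
#' reinforcement learner with learning rates `t_pot`, `t_dep`.
#'
#' @param t_pot Potentiation rate in `[0, 1]`.
#' @param t_dep Depression rate in `[0, 1]`; defaults to `t_pot`.
#' @return An object of class `metaplastic_model` with `n_states = 2`.
#' @export
build_binary_model <- function(t_pot, t_dep = t_pot) {
  if (t_pot < 0 || t_pot > 1 || t_dep < 0 || t_dep > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  pot <- matrix(c(1 - t_pot, t_pot, 0, 1), 2, 2)
  dep <- matrix(c(1, 0, t_dep, 1 - t_dep), 2, 2)
  new_metaplastic_model(2L, pot, dep, c(-1, 1), "binary",
                        c(t_pot = t_pot, t_dep = t_dep))
}

#' Build a one-parameter ladder ("superior family") metaplastic model
#'
#' The single-parameter family: potentiation moves each meta-state exactly
#' one step toward the deep-strong end with probability `q`; all
#' longer-range potentiation rates are zero; depression is the mirror
#' image. For `N = 4` this leaves three of the six free potentiation rates
#' nonzero. Despite having one parameter, members of this family strongly
#' mitigate the adaptability-precision tradeoff.
#'
#' @param q Transition probability in `[0, 1]`.
#' @param n_states Even integer, number of meta-states.
#' @return An object of class `metaplastic_model`.
#' @export
build_one_parameter_model <- function(q, n_states) {
  n <- check_n_states(n_states)
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  idx <- rate_index(n)
  params <- ifelse(idx$dest == idx$source + 1L, q, 0)
  m <- build_symmetric_model(params, n)
  m$family <- "one_param"
  m$params <- c(q = q)
  m
}

# Depth of each state: distance from the plastic boundary (1 = shallowest).
state_depth <- function(n_states) {
  half <- n_states / 2
  c(half:1, 1:half)
}

#' Build a cascade metaplastic model
#'
#' Cascade topology: on rewarded trials every weak state makes a plastic
#' jump into the shallowest strong state, while strong states make
#' metaplastic transitions one step deeper; depression is the mirror image.
#' Rates form a geometric cascade in the depth `d` of the source state,
#' `q^d`, so deeper states are exponentially more stable and the whole
#' cascade is controlled by the single base rate `q`. This structure
#' preserves stored signal at the cost of adaptability.
#'
#' @inheritParams build_one_parameter_model
#' @return An object of class `metaplastic_model`.
#' @export
build_cascade_model <- function(q, n_states) {
  n <- check_n_states(n_states)
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  half <- n / 2
  depth <- state_depth(n)
  pot <- matrix(0, n, n)
  for (i in seq_len(half)) {                 # weak source: plastic jump
    pot[half + 1L, i] <- q^depth[i]
  }
  if (half > 1) {
    for (i in (half + 1L):(n - 1L)) {        # strong source: deepen
      pot[i + 1L, i] <- q^depth[i]
    }
  }
  dep <- reflect_matrix(pot)
  pot <- set_diagonal_remainder(pot)
  dep <- set_diagonal_remainder(dep)
  new_metaplastic_model(n, pot, dep, default_efficacies(n),
                        "cascade", c(q = q))
}

#' Build a reward-dependent metaplasticity (RDMP) model
#'
#' A heuristic metaplasticity model: potentiation moves each state one step
#' toward the deep-strong end along a nearest-neighbour ladder (so the
#' plastic boundary is crossed only from the shallowest weak state), with
#' rates decaying geometrically in the depth of the source state,
#' `q * (1/2)^(d - 1)`; depression is the mirror image. The original model
#' is defined only by reference in the literature; this ladder with
#' depth-decaying rates is an approximation of it.
#'
#' @inheritParams build_one_parameter_model
#' @return An object of class `metaplastic_model`.
#' @export
build_rdmp_model <- function(q, n_states) {
  n <- check_n_states(n_states)
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  depth <- state_depth(n)
  pot <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    pot[i + 1L, i] <- q * 0.5^(depth[i] - 1)
  }
  dep <- reflect_matrix(pot)
  pot <- set_diagonal_remainder(pot)
  dep <- set_diagonal_remainder(dep)
  new_metaplastic_model(n, pot, dep, default_efficacies(n),
                        "rdmp", c(q = q))
}

check_efficacies <- function(efficacies) {
  n <- length(efficacies)
  if (n < 2 || n %% 2 != 0) {
    stop("efficacies must have even length >= 2", call. = FALSE)
  }
  if (any(abs(efficacies) > 1 + 1e-12)) {
    stop("efficacy magnitudes must be <= 1", call. = FALSE)
  }
  if (max(abs(efficacies + rev(efficacies))) > 1e-12) {
    stop("efficacies must be antisymmetric (value at i = -value at N+1-i)",
         call. = FALSE)
  }
  if (any(diff(efficacies) < -1e-12)) {
    stop("efficacies must be nondecreasing in state index", call. = FALSE)
  }
  invisible(efficacies)
}

#' Build a graded plastic model
#'
#' Same nearest-neighbour ladder topology as [build_one_parameter_model()],
#' but with graded synaptic efficacies assigned to the inner states, so
#' formerly metaplastic transitions change efficacy. Setting all magnitudes
#' to 1 recovers the metaplastic model exactly.
#'
#' @param q Transition probability in `[0, 1]`.
#' @param efficacies Numeric vector of even length: antisymmetric
#'   (`efficacies[i] == -efficacies[N+1-i]`), nondecreasing, magnitudes
#'   at most 1 (e.g. `c(-1, -0.5, 0.5, 1)`).
#' @return An object of class `metaplastic_model`.
#' @export
build_graded_model <- function(q, efficacies) {
  check_efficacies(efficacies)
  m <- build_one_parameter_model(q, length(efficacies))
  m$efficacies <- efficacies
  m$family <- "graded"
  m$params <- c(q = q, w = efficacies)
  m
}

#' Validate a metaplastic model
#'
#' Checks every structural invariant: entries in `[0, 1]`, per-source-state
#' probability conservation (columns sum to 1), the triangular flow
#' directions (potentiation toward the deep-strong end, depression toward
#' the deep-weak end), and the efficacy vector (antisymmetric,
#' nondecreasing, magnitudes at most 1).
#'
#' @param model A `metaplastic_model`.
#' @return Character vector of human-readable violations; empty if the
#'   model is valid.
#' @export
validate_model <- function(model) {
  v <- character(0)
  n <- model$n_states
  for (nm in c("potentiation", "depression")) {
    m <- model[[nm]]
    if (!is.matrix(m) || any(dim(m) != n)) {
      v <- c(v, sprintf("%s: not an %d x %d matrix", nm, n, n))
      next
    }
    bad <- which(m < -1e-12 | m > 1 + 1e-12)
    if (length(bad) > 0) {
      v <- c(v, sprintf("%s: entry outside [0, 1] at linear index %s",
                        nm, paste(bad, collapse = ", ")))
    }
    cs <- colSums(m)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad) > 0) {
      v <- c(v, sprintf("%s: outflow from source state %s does not sum to 1",
                        nm, paste(bad, collapse = ", ")))
    }
    off <- m
    diag(off) <- 0
    ij <- which(off > 1e-15, arr.ind = TRUE)
    if (nm == "potentiation") {
      wrong <- ij[ij[, "row"] < ij[, "col"], , drop = FALSE]
      if (nrow(wrong) > 0) {
        v <- c(v, sprintf(
          "potentiation: flow toward the weak end from state %s",
          paste(unique(wrong[, "col"]), collapse = ", ")))
      }
    } else {
      wrong <- ij[ij[, "row"] > ij[, "col"], , drop = FALSE]
      if (nrow(wrong) > 0) {
        v <- c(v, sprintf(
          "depression: flow toward the strong end from state %s",
          paste(unique(wrong[, "col"]), collapse = ", ")))
      }
    }
  }
  e <- model$efficacies
  if (length(e) != n) {
    v <- c(v, "efficacies: wrong length")
  } else {
    if (any(abs(e) > 1 + 1e-12)) v <- c(v, "efficacies: magnitude above 1")
    if (max(abs(e + rev(e))) > 1e-12) v <- c(v, "efficacies: not antisymmetric")
    if (any(diff(e) < -1e-12)) v <- c(v, "efficacies: not nondecreasing")
  }
  v
}

#' @export
print.metaplastic_model <- function(x, ...) {
  cat(sprintf("<metaplastic_model> family = %s, N = %d\n", x$family,
              x$n_states))
  cat("parameters:", paste(signif(x$params, 4), collapse = " "), "\n")
  cat("efficacies:", paste(x$efficacies, collapse = " "), "\n")
  invisible(x)
}
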