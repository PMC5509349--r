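---
title: "Metaplastic synapse models: methods and design choices"
author: "metaplastr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaplastic synapse models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplastr)
```

## The estimation problem and the model

A population of binary-efficacy synapses estimates the probability `p_r`
of a binary reward. Each synapse occupies one of `N` ordered meta-states:
states `1..N/2` express weak efficacy (−1), states `N/2+1..N` strong
efficacy (+1), and within each efficacy class states are ordered by
*depth* (state 1 is the deepest weak state, state `N` the deepest strong
state). On a rewarded trial every synapse transitions according to the
potentiation matrix; on an unrewarded trial according to the depression
matrix. The *signal* `S`, the difference between the fractions of strong
and weak synapses, carries the probability estimate.

Three structural assumptions define the model class:

* **Ordered flow.** Potentiation only moves synapses toward the
  deep-strong end (destination index above source index); depression only
  toward the deep-weak end. The matrices are therefore triangular.
* **Mirror symmetry.** Reward and no-reward are informationally
  symmetric: relabelling states `i -> N+1-i` and swapping the two matrices
  leaves the model unchanged. This fixes the depression matrix from the
  potentiation matrix and leaves `N(N-1)/2` free rates.
* **Probability conservation.** The outgoing rates from each state
  (including the implicit stay probability on the diagonal) sum to one.

Matrix convention: occupancy is a column vector updated as
`new = M %*% old`; *columns* index source states and sum to 1. The
reflection is implemented as `i -> N+1-i` under 1-based indexing, which is
the only reading that preserves the mirror symmetry. Stay probabilities
are never free parameters; they are the diagonal remainder.

## Mean-field quantities

At fixed `p_r` the averaged matrix is
`T-bar = p_r * T_pot + (1 - p_r) * T_dep`. The package computes:

* **Steady state**: the Perron eigenvector of `T-bar` at eigenvalue 1,
  via eigen-decomposition with a bordered linear solve as fallback.
  Uniqueness requires every other eigenvalue modulus to be below
  `1 - 1e-8`; chains violating this (all-zero rates, absorbing ends at
  `p_r` of 0 or 1) are reported as degenerate rather than analysed.
* **One-step noise** `eta`: the reward-weighted absolute signal change
  caused by one potentiation or depression event applied at steady state.
  It counts only the noise generated in a single trial and is a lower
  bound on simulation noise.
* **Sensitivity** `dS/dp_r`: central finite difference with step 0.005.
  The step is small enough that the quadratic truncation error is far
  below any tolerance used here, and large enough to stay clear of
  eigen-solver jitter. At the interval boundaries a one-sided difference
  is used and flagged.
* **Precision**: sensitivity divided by one-step noise — how well the
  settled signal discriminates adjacent reward probabilities.
* **Adaptability**: the spectral gap `1 - |lambda_2|`. "Second-largest
  eigenvalue" is read as second-largest *modulus*: eigenvalues of
  non-reversible chains can be complex and the modulus is what governs the
  asymptotic per-trial decay.
* **Effective learning rates**: the single pair of boundary-crossing
  rates a two-state model would need to reproduce the plastic flow out of
  the steady state; they rise (potentiation) and fall (depression) with
  `p_r` and cross at 0.5 for mirror-symmetric models.
* **Subset flows**: for all `2^N - 2` proper subsets, the effective
  transition rate (outward flow over subset occupancy) and the Markov
  conductance (outward flow over the smaller of the two occupancies). The
  subset minimizing the effective rate is reported as the bottleneck. For
  optimized superior models this bottleneck separates the weak from the
  strong side — the structural signature of noise reduction at minimal
  adaptability cost. For the one-parameter ladder the literal argmin can
  instead be a deep-end subset (its occupancy is large and its outward
  flow diffusive), so bottleneck claims are made for optimized models.

Averages of adaptability and precision are taken over the grid 0.05 to
0.95 in steps of 0.05. The endpoints are excluded because absorbing
topologies lose steady-state uniqueness there; the grid itself is a
configuration knob since no canonical grid exists for this average.

For the two-state model every quantity has a closed form derived from the
balance equation `p t+ (1 - psi_s) = (1 - p) t- psi_s`; the test suite
pins the matrix implementation to those closed forms at 1e-10 and checks
the parameter-free law `A * P = 1 / (2 p (1 - p))`.

## Monte Carlo simulations

`simulate_population()` updates integer state counts by multinomial draws
per source state (decomposed into sequential binomials so a whole ensemble
of populations stays vectorized). Ensembles are advanced in a single
seeded random stream rather than per-instance substreams: the vectorized
update makes one stream both faster and exactly reproducible from one
integer seed.

**Ensemble noise** is the across-instance standard deviation of the
signal after a 500-trial burn-in at fixed `p_r`, starting from the
mean-field steady state. An ensemble (not temporal) estimator avoids
autocorrelation corrections. It always exceeds the one-step noise, which
omits transferred and finite-size fluctuations.

**Convergence rate** after a jump in reward probability (0.3 to 0.8 by
default) is measured by fitting a single exponential to the ensemble-mean
signal. Three estimator choices matter and were made deliberately:

1. *Batch means*: the reported rate is the mean of ten sub-ensemble fits
   and its standard error the spread across them, so the estimate and its
   uncertainty are commensurate.
2. *Deterministic fit window, fitted in signal space*: the window (by
   default where the remaining gap is between 2% and 50% of its initial
   value) is located on the *exact* mean-field trajectory — the
   expectation of every simulated path — and the exponential is fitted by
   least squares on the raw gap. Fitting `log |gap|` instead would turn
   the noise floor into a systematic flattening of the tail; at
   1000 synapses that artefact masquerades as a ~0.5% finite-size bias.
3. *A comparable reference*: a single exponential fitted over a finite
   window of a multi-mode relaxation is deterministically offset from the
   spectral gap (by −0.1% to −1% for four-state ladders, because the
   subdominant mode enters with opposite sign). The returned
   `mf_adaptability` is therefore the same fit applied to the exact
   mean-field path, and the raw `spectral_gap` is reported alongside.
   Comparing identically fitted rates isolates the Monte Carlo error,
   which is the quantity of interest when validating the simulation.

Defaults are 1000 synapses and 10^4 instances; these sizes keep every
simulation-based check in the test suite within seconds while leaving
standard errors in the 1e-4 range, and both are arguments.

## Finding superior models

The frontier search maximizes the product of grid-averaged adaptability
and precision for a given precision, in two stages. Stage one draws
random parameter vectors — independent uniforms on [0, 1] per free rate,
rejection-resampled until every source outflow is at most 1 — scores them
(a compiled RcppArmadillo routine evaluates the steady state, spectral
gap, noise, and sensitivity for batches of models; it is tested to agree
with the R implementation to 1e-10), bins them into 20 equal-width bins
over the observed average-precision range, and keeps each bin's best
model. Stage two runs Nelder-Mead from each incumbent and from a jittered
duplicate (multiplicative Gaussian jitter, scale 0.05), with penalties
for infeasible rates and a soft pull (weight 1e-3 of the objective) back
toward the bin's precision center; a candidate replaces the incumbent
only if it improves the raw objective, so per-bin objectives never
decrease. At the default desk scale (1e5 samples, 3 iterations, N = 4)
the refined models in essentially all bins have exactly three near-zero
free potentiation rates (below 1% of the largest rate) — the nearest-
neighbour ladder — and their flow bottleneck sits at the plastic
boundary.

States are classified from the topology: *buffers* take part in an
above-tolerance efficacy-changing transition; the deepest weak and strong
states are *reservoirs* when they are not buffers; remaining states are
*transients* routing synapses between the two. The zero tolerance is 1%
of the largest rate in the matrices.

The one-parameter family (all nearest-neighbour rates equal to `q`) has a
notable invariance: its steady state, and hence signal, sensitivity-to-
noise ratio and the product of average adaptability and precision, do not
depend on `q`; `q` only trades precision against adaptability along a
fixed-objective line. The family's objective rises with the number of
meta-states (N = 8 over 6 over 4 over 2 at matched precision).

Equivalent-binary comparisons follow the optimized models: an optimized
superior model beats the two-state model built from its own effective
learning rates in sensitivity, precision *and* adaptability at every
grid `p_r`. The one-parameter ladder beats its equivalent binary model in
sensitivity and precision but not in spectral gap — its end-to-end
diffusion is slower than the matched two-state chain — which is why
dominance claims in the tests are made for optimized models.

## The probability-estimation task

The environment holds the true reward probability on the lattice
`{0, 0.1, ..., 1}` (11 levels), stepping ±0.1 with equal probability
every `L` trials; at the lattice ends the step reflects inward, and the
walk starts at 0.5 (both choices are conventions — the sources leave them
open). In the complex environment the block length is drawn from
`{10, ..., 100}`, always preferring the value with the least accumulated
trials so exposure per volatility level stays balanced.

Learners are updated deterministically from a shared Bernoulli reward
sequence (same seed, same rewards, for every learner): synaptic learners
propagate an infinite-population occupancy through the potentiation or
depression matrix; the delta rule updates `V <- V + alpha (r - V)`; the
Bayesian reference is a grid filter over probability (50 points),
volatility (30 log-spaced points controlling the spread of a Beta
transition kernel centred on the previous probability) and a static
volatility-scale hyperparameter (15 log-spaced points governing a
log-normal volatility random walk). The Bayesian learner is a
reconstruction — the original is specified only by citation — and all its
grid sizes are arguments.

Errors are scored on the probability scale, `p-hat = (S + 1) / 2` for
synaptic learners: *relative* error is the distance to the learner's own
steady-state estimate at the current true probability (how quickly it
reaches what it would settle on), *absolute* error the distance to the
truth. The probability scale makes the two families of learners directly
comparable and reduces to `mean |V - p|` for the delta rule.

The cascade model's rates are `q^depth` — a geometric cascade in the base
rate itself, as in the cascade-synapse literature. A variant with a fixed
ratio of 1/2 per depth level was evaluated and rejected: it makes the
cascade an excellent tracker, erasing the characteristic cost of
signal-preserving depth that distinguishes cascade models in this task.
The RDMP learner is a nearest-neighbour ladder with `(1/2)^(depth-1)`
rate decay whose boundary is crossed only from the shallowest states;
the original heuristic is defined only by citation, so this topology is
an approximation and no benchmark ordering is asserted for it.

## Robustness analyses

`perturb_model()` multiplies every nonzero off-diagonal rate by
`1 + fraction * z` (standard normal `z`), truncates at 1e-6 — keeping
rates positive with minimal distortion, rather than resampling — and
recomputes the stay probabilities; columns whose outflow would exceed 1
are proportionally rescaled and flagged. The zero pattern, i.e. the
transition topology, is always preserved. Ten-percent perturbations of a
six-state ladder move its average adaptability-precision objective by
well under 25% and never push it down to the two-state tradeoff curve.

`graded_sweep()` assigns intermediate efficacy magnitudes to the inner
states of the ladder topology, so formerly metaplastic transitions change
efficacy. All mean-field quantities use the graded efficacy vector
directly, and the unit-magnitude corner reproduces the metaplastic model
through the identical code path. The objective increases monotonically
toward that corner.

## What the synthetic conditions do and do not show

All inputs are synthetic by construction (the task itself is a model):
Bernoulli rewards, lattice random-walk probabilities, and populations of
identical, independent synapses. Passing tests therefore demonstrate
internal consistency of the theory, the simulations and the optimizer —
not that biological synapses implement these transition structures, and
not performance under reward statistics that drift continuously, are
non-stationary within blocks, or couple synapses through shared
neuromodulation. Estimator caveats: the ensemble noise and decay-rate
measurements assume stationarity after burn-in and a dominant single
decay mode within the fit window; both assumptions are checked indirectly
(noise bound, agreement with the fitted mean-field reference) but can
fail for nearly-degenerate chains.

Problem sizes used throughout the tests — 1e5 optimizer samples, 10^4
Monte Carlo instances of 1000 synapses, benchmark runs of a few thousand
trials — were chosen as the smallest sizes at which every qualitative
conclusion is stable across seeds; all are arguments, and the larger
published-scale settings (1e7 samples, 1e5 instances) are plain parameter
changes.
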