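test_that("average transition interpolates the two matrices", {
  m <- build_one_parameter_model(0.2, 4)
  expect_identical(average_transition(m, 1), m$potentiation)
  expect_identical(average_transition(m, 0), m$depression)
  b <- build_binary_model(0.1)
  expect_equal(average_transition(b, 0.5),
               matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2))
  expect_error(average_transition(m, 1.2), "p_r")
})

test_that("all two-state quantities match the balance-equation oracle", {
  set.seed(23)
  for (rep in 1:200) {
    t_pot <- stats::runif(1, 0.01, 0.9)
    t_dep <- stats::runif(1, 0.01, 0.9)
    p <- stats::runif(1, 0.05, 0.95)
    b <- build_binary_model(t_pot, t_dep)
    o <- binary_oracle(t_pot, t_dep, p)
    expect_equal(steady_state(b, p), o$occupancy, tolerance = 1e-10)
    expect_equal(synaptic_signal(steady_state(b, p), b$efficacies),
                 o$signal, tolerance = 1e-10)
    expect_equal(one_step_noise(b, p), o$noise, tolerance = 1e-10)
    expect_equal(adaptability(b, p), o$adaptability, tolerance = 1e-10)
    tr <- effective_learning_rates(b, p)
    expect_equal(unname(tr), c(o$eff_pot, o$eff_dep), tolerance = 1e-10)
  }
})

test_that("steady state is a fixed point and flags degenerate chains", {
  set.seed(29)
  for (n in c(4, 6)) {
    for (rep in 1:30) {
      m <- build_symmetric_model(random_valid_params(n), n)
      p <- stats::runif(1, 0.05, 0.95)
      psi <- steady_state(m, p)
      expect_true(all(psi >= 0))
      expect_equal(sum(psi), 1, tolerance = 1e-12)
      expect_lt(max(abs(average_transition(m, p) %*% psi - psi)), 1e-12)
    }
  }
  idm <- build_one_parameter_model(0, 4)
  expect_error(steady_state(idm, 0.5), "non-unique")
  expect_error(adaptability(idm, 0.5), "non-unique")
})

test_that("symmetric models obey the reflection symmetries", {
  m <- build_one_parameter_model(0.2, 6)
  for (p in c(0.1, 0.3, 0.45)) {
    expect_equal(steady_signal_ <- metaplastr:::steady_signal(m, p),
                 -metaplastr:::steady_signal(m, 1 - p), tolerance = 1e-12)
    expect_equal(one_step_noise(m, p), one_step_noise(m, 1 - p),
                 tolerance = 1e-12)
    tr <- effective_learning_rates(m, p)
    tr_ref <- effective_learning_rates(m, 1 - p)
    expect_equal(tr[["pot"]], tr_ref[["dep"]], tolerance = 1e-12)
  }
  # occupancy at p = 0.5 is invariant under state reflection
  psi <- steady_state(m, 0.5)
  expect_equal(psi, rev(psi), tolerance = 1e-12)
})

test_that("sensitivity behaves as the closed form and at boundaries", {
  b <- build_binary_model(0.07)
  for (p in c(0.2, 0.5, 0.8)) {
    expect_equal(as.numeric(sensitivity(b, p)), 2, tolerance = 1e-6)
  }
  s <- sensitivity(b, 0.001)
  expect_true(attr(s, "one_sided"))
  s <- sensitivity(b, 0.5)
  expect_false(attr(s, "one_sided"))
})

test_that("precision matches the closed form and scales with 1/t", {
  b <- build_binary_model(0.1)
  expect_equal(estimation_precision(b, 0.5), 20, tolerance = 1e-6)
  b2 <- build_binary_model(0.05)
  expect_equal(estimation_precision(b2, 0.5),
               2 * estimation_precision(b, 0.5), tolerance = 1e-6)
})

test_that("adaptability times precision is parameter-free for binary models", {
  for (t in seq(0.01, 0.5, by = 0.07)) {
    b <- build_binary_model(t)
    for (p in c(0.25, 0.5, 0.7)) {
      expect_equal(adaptability(b, p) * estimation_precision(b, p),
                   1 / (2 * p * (1 - p)), tolerance = 1e-6)
    }
  }
})

test_that("effective learning rates adjust to reward probability", {
  m <- build_one_parameter_model(0.2, 6)
  grid <- seq(0.05, 0.95, by = 0.05)
  tr <- vapply(grid, function(p) effective_learning_rates(m, p), numeric(2))
  expect_true(all(diff(tr["pot", ]) >= -1e-12))  # pot rate nondecreasing
  expect_true(all(diff(tr["dep", ]) <= 1e-12))   # dep rate nonincreasing
  at_half <- effective_learning_rates(m, 0.5)
  expect_equal(at_half[["pot"]], at_half[["dep"]], tolerance = 1e-12)
  # a binary model reports its own rates
  b <- build_binary_model(0.3, 0.12)
  expect_equal(unname(effective_learning_rates(b, 0.4)), c(0.3, 0.12),
               tolerance = 1e-12)
})

test_that("metaplastic models beat their equivalent binary models", {
  eb0 <- equivalent_binary_model(build_binary_model(0.2, 0.1), 0.3)
  expect_equal(unname(eb0$params), c(0.2, 0.1), tolerance = 1e-12)

  # the one-parameter ladder dominates in sensitivity and precision
  m <- build_one_parameter_model(0.2, 6)
  for (p in default_p_r_grid()) {
    eb <- equivalent_binary_model(m, p)
    expect_gte(as.numeric(sensitivity(m, p)),
               as.numeric(sensitivity(eb, p)) - 1e-9)
    expect_gte(estimation_precision(m, p),
               estimation_precision(eb, p) - 1e-9)
  }
  # an optimized superior model dominates in all three quantities
  sup <- superior_n4()
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    eb <- equivalent_binary_model(sup, p)
    expect_gte(as.numeric(sensitivity(sup, p)),
               as.numeric(sensitivity(eb, p)) - 1e-9)
    expect_gte(estimation_precision(sup, p),
               estimation_precision(eb, p) - 1e-9)
    expect_gte(adaptability(sup, p), adaptability(eb, p) - 1e-9)
  }
})

test_that("subset flows enumerate 2^N - 2 subsets with coherent rates", {
  m <- build_one_parameter_model(0.2, 4)
  sf <- subset_flows(m, 0.5)
  expect_identical(nrow(sf), 14L)
  small <- sf$occupancy_mass <= 0.5
  expect_true(all(sf$conductance[small] >= sf$eff_rate[small] - 1e-12))

  b <- build_binary_model(0.1)
  sfb <- subset_flows(b, 0.3)
  weak_row <- sfb[sfb$subset == "1", ]
  expect_equal(weak_row$eff_rate, 0.3 * 0.1, tolerance = 1e-12)
  expect_error(subset_flows(build_one_parameter_model(0.1, 14), 0.5),
               "n_states <= 12")
})

test_that("mf_summary aggregates and preserves definitional identities", {
  b <- build_binary_model(0.1)
  s <- mf_summary(b, c(0.25, 0.5, 0.75))
  av <- attr(s, "averages")
  expect_equal(av$avg_adaptability, 0.1, tolerance = 1e-12)
  expect_equal(s$precision * s$one_step_noise, s$sensitivity,
               tolerance = 1e-9)

  m <- build_one_parameter_model(0.15, 6)
  full <- mf_summary(m, seq(0.1, 0.9, by = 0.1))
  # signal is sigmoid: nondecreasing in p_r
  expect_true(all(diff(full$signal) >= -1e-12))
  # reflection-closed grid: mean adaptability equals the half-grid mean
  lower <- mf_summary(m, seq(0.1, 0.4, by = 0.1))
  expect_equal(attr(full, "averages")$avg_adaptability,
               mean(c(lower$adaptability, adaptability(m, 0.5),
                      rev(lower$adaptability))), tolerance = 1e-10)
  # degenerate points are skipped and reported
  idm <- build_one_parameter_model(0, 4)
  expect_error(mf_summary(idm, c(0, 0.5)), "inside")
})
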