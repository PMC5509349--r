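test_that("the schedule walks the 11-level probability lattice", {
  env <- make_environment(10, 30000, seed = 2)
  levels <- sort(unique(env$p_path))
  expect_identical(length(levels), 11L)
  expect_equal(levels, seq(0, 1, by = 0.1), tolerance = 1e-12)
  # steps between blocks are exactly +/- 0.1
  changes <- rle(env$p_path)$values
  expect_true(all(abs(abs(diff(changes)) - 0.1) < 1e-12))
})

test_that("block structure and determinism hold", {
  env <- make_environment(20, 200, seed = 7)
  expect_identical(length(env$block_lengths), 10L)
  expect_true(all(env$block_lengths == 20))
  env2 <- make_environment(20, 200, seed = 7)
  expect_identical(env$p_path, env2$p_path)
  expect_error(make_environment(0, 100), "positive")
})

test_that("the complex environment balances exposure across block lengths", {
  Ls <- seq(10, 100, by = 10)
  env <- make_environment(Ls, 20000, seed = 11)
  expect_true(all(env$block_lengths %in% c(Ls, 1:100)))
  totals <- tapply(env$block_lengths, env$block_lengths, sum)
  full <- totals[names(totals) %in% as.character(Ls)]
  # trials per L value stay within a factor ~2 of each other
  expect_lt(max(full) / min(full), 2.5)
})

test_that("the delta rule with unit learning rate echoes the last reward", {
  env <- make_environment(50, 300, seed = 3)
  tr <- run_learner(learner_delta(1), env, seed = 9)
  expect_equal(tr$estimate, as.numeric(tr$rewards))
})

test_that("reward draws depend only on the seed, not on the learner", {
  env <- make_environment(50, 200, seed = 3)
  t1 <- run_learner(learner_delta(0.1), env, seed = 9)
  t2 <- run_learner(learner_synaptic(build_one_parameter_model(0.2, 6)),
                    env, seed = 9)
  expect_identical(t1$rewards, t2$rewards)
  t3 <- run_learner(learner_delta(0.1), env, seed = 9)
  expect_identical(t1$estimate, t3$estimate)
})

test_that("the delta rule equals the binary plastic mean-field learner", {
  env <- make_environment(40, 400, seed = 5)
  a <- run_learner(learner_delta(0.12), env, seed = 6)
  b <- run_learner(learner_synaptic(build_binary_model(0.12)), env, seed = 6)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
})

test_that("a deterministic reward stream drives the learner to fixation", {
  m <- build_one_parameter_model(0.2, 6)
  tr <- run_learner(learner_synaptic(m), rep(1, 300), seed = 4)
  expect_lt(abs(tr$estimate[300] - 1), 1e-6)
  # and the averaged-map fixed point matches steady_state
  p <- 0.7
  tbar <- average_transition(m, p)
  psi <- rep(1 / 6, 6)
  for (i in 1:3000) psi <- drop(tbar %*% psi)
  expect_lt(max(abs(psi - steady_state(m, p))), 1e-10)
})

test_that("error measures reduce to their defining special cases", {
  env <- make_environment(25, 250, seed = 13)
  # a trace that sits exactly on the steady map has zero relative error
  lr <- learner_delta(0.2)
  perfect <- structure(list(estimate = env$p_path, learner = lr),
                       class = "estimate_trace")
  expect_equal(relative_error(perfect, env), 0)
  expect_equal(absolute_error(perfect, env), 0)
  # constant 0.5 estimate: absolute error is the mean lattice distance
  flat <- structure(list(estimate = rep(0.5, 250), learner = lr),
                    class = "estimate_trace")
  expect_equal(absolute_error(flat, env), mean(abs(env$p_path - 0.5)))
  # delta-rule relative error is mean |V - p|
  tr <- run_learner(lr, env, seed = 14)
  expect_equal(relative_error(tr, env),
               mean(abs(tr$estimate - env$p_path)), tolerance = 1e-12)
})

test_that("superior models are flat in their parameter; error orderings hold", {
  qs <- c(0.05, 0.12, 0.2, 0.35, 0.5)
  env_seed <- 101
  rel_sup <- rel_rl <- abs_sup <- abs_rl <- rel_cas <- numeric(0)
  for (rep in 1:3) {
    env <- make_environment(100, 1200, seed = env_seed + rep)
    for (q in qs) {
      m <- build_one_parameter_model(q, 6)
      trs <- run_learner(learner_synaptic(m), env, seed = env_seed + rep)
      trr <- run_learner(learner_delta(q), env, seed = env_seed + rep)
      trc <- run_learner(learner_synaptic(build_cascade_model(q, 6)), env,
                         seed = env_seed + rep)
      rel_sup <- c(rel_sup, relative_error(trs, env))
      rel_rl <- c(rel_rl, relative_error(trr, env))
      rel_cas <- c(rel_cas, relative_error(trc, env))
      abs_sup <- c(abs_sup, absolute_error(trs, env))
      abs_rl <- c(abs_rl, absolute_error(trr, env))
    }
  }
  by_q <- function(x) tapply(x, rep(qs, 3), mean)
  # near-optimal over a wide parameter range: flatter than the delta rule
  expect_lt(max(by_q(rel_sup)) / min(by_q(rel_sup)),
            max(by_q(rel_rl)) / min(by_q(rel_rl)))
  # the cascade model preserves signal and pays in relative error:
  # clearly at small rates where its deep states barely move, and on
  # average over the sweep
  small <- as.character(qs[qs <= 0.2])
  expect_true(all(by_q(rel_cas)[small] > by_q(rel_sup)[small]))
  expect_gt(mean(by_q(rel_cas)), mean(by_q(rel_sup)))
  # under the absolute metric the superior family's biased signal loses
  expect_gt(min(by_q(abs_sup)), min(by_q(abs_rl)))
})

test_that("the benchmark table carries a parameter-free Bayesian row", {
  specs <- list(
    superior = list(make = function(q) {
      learner_synaptic(build_one_parameter_model(q, 6))
    }, grid = c(0.1, 0.3)),
    rl = list(make = function(a) learner_delta(a), grid = c(0.1, 0.3)),
    bayes = list(make = function() {
      learner_bayesian(n_p = 20, n_v = 10, n_k = 5)
    }, grid = NULL)
  )
  res <- benchmark_learners(specs,
                            environments = list(L20 = list(L = 20,
                                                           n_trials = 200)),
                            n_reps = 2, seed = 3)
  expect_setequal(unique(res$learner), c("superior", "rl", "bayes"))
  bay <- res[res$learner == "bayes", ]
  expect_true(all(is.na(bay$parameter)))
  expect_true(all(res$mean >= 0))
  expect_setequal(unique(res$metric), c("relative", "absolute"))
})
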