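test_that("every constructor produces models passing validation", {
  set.seed(11)
  models <- list(
    build_binary_model(0.3, 0.1),
    build_one_parameter_model(0.25, 6),
    build_cascade_model(0.4, 6),
    build_rdmp_model(0.4, 8),
    build_graded_model(0.2, c(-1, -0.5, 0.5, 1))
  )
  for (n in c(2, 4, 6)) {
    for (rep in 1:20) {
      models[[length(models) + 1]] <-
        build_symmetric_model(random_valid_params(n), n)
    }
  }
  for (m in models) expect_length(validate_model(m), 0)
})

test_that("symmetric construction enforces its preconditions", {
  expect_error(build_symmetric_model(c(0.1, 0.2), 4), "length 6")
  expect_error(build_symmetric_model(c(-0.1, 0, 0, 0, 0, 0), 4), "negative")
  # source state 1 has three outgoing rates summing to 1.5
  expect_error(build_symmetric_model(c(0.5, 0.5, 0.5, 0, 0, 0), 4),
               "state.* 1")
  expect_error(build_symmetric_model(c(0.1), 3), "even")
})

test_that("reflection is an involution and links the two matrices", {
  set.seed(7)
  for (rep in 1:100) {
    m <- build_symmetric_model(random_valid_params(4), 4)
    r <- metaplastr:::reflect_matrix
    expect_identical(r(r(m$potentiation)), m$potentiation)
    expect_identical(r(m$potentiation), m$depression)
  }
})

test_that("the one-parameter family has the printed ladder structure", {
  m0 <- build_one_parameter_model(0, 4)
  expect_identical(m0$potentiation, diag(4))
  expect_identical(m0$depression, diag(4))

  m <- build_one_parameter_model(0.2, 4)
  idx <- rate_index(4)
  free <- m$potentiation[cbind(idx$dest, idx$source)]
  expect_identical(sum(free > 0), 3L)           # three of six are nonzero
  expect_true(all(free[free > 0] == 0.2))

  # N = 2 member coincides with the general symmetric construction
  expect_equal(build_one_parameter_model(0.3, 2)$potentiation,
               build_symmetric_model(0.3, 2)$potentiation)
})

test_that("the symmetric family exposes N(N-1)/2 free rates", {
  expect_identical(n_unique_rates(4), 6L)
  expect_identical(n_unique_rates(6), 15L)
  expect_identical(nrow(rate_index(8)), n_unique_rates(8))
})

test_that("cascade rates decay geometrically with depth", {
  m <- build_cascade_model(0.4, 6)
  # deepest weak state (index 1, depth 3) jumps the boundary at q^3
  expect_equal(m$potentiation[4, 1], 0.4^3)
  expect_equal(m$potentiation[4, 3], 0.4)       # shallowest weak, depth 1
  expect_equal(colSums(m$potentiation), rep(1, 6))
  expect_equal(colSums(m$depression), rep(1, 6))
  # no depth at N = 2: plain binary model
  expect_equal(build_cascade_model(0.3, 2)$potentiation,
               build_binary_model(0.3)$potentiation)
})

test_that("rdmp reduces correctly and conserves probability", {
  expect_identical(build_rdmp_model(0, 6)$potentiation, diag(6))
  expect_equal(build_rdmp_model(0.25, 2)$potentiation,
               build_binary_model(0.25)$potentiation)
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(c(2, 4, 6, 8), 1)
    m <- build_rdmp_model(stats::runif(1), n)
    expect_equal(colSums(m$potentiation), rep(1, n))
    expect_equal(colSums(m$depression), rep(1, n))
  }
})

test_that("graded models accept valid efficacies and reject invalid ones", {
  g <- build_graded_model(0.2, c(-1, -1, 1, 1))
  m <- build_one_parameter_model(0.2, 4)
  expect_equal(g$potentiation, m$potentiation)
  expect_equal(synaptic_signal(rep(0.25, 4), c(-1, -0.5, 0.5, 1)), 0)
  expect_silent(build_graded_model(0.1, c(-1, 0, 0, 1)))
  expect_error(build_graded_model(0.1, c(-1, 0.5, -0.5, 1)),
               "nondecreasing|antisymmetric")
  expect_error(build_graded_model(0.1, c(-1, -0.5, 0.4, 1)), "antisymmetric")
  expect_error(build_graded_model(0.1, c(-2, -1, 1, 2)), "magnitude")
})

test_that("validate_model reports broken invariants precisely", {
  m <- build_one_parameter_model(0.2, 4)
  expect_length(validate_model(m), 0)

  bad <- m
  bad$potentiation[1, 1] <- bad$potentiation[1, 1] - 0.1
  v <- validate_model(bad)
  expect_true(any(grepl("potentiation.*sum to 1", v)))

  bad <- m
  bad$potentiation[1, 3] <- 0.05                # flow toward the weak end
  bad$potentiation[3, 3] <- bad$potentiation[3, 3] - 0.05
  v <- validate_model(bad)
  expect_true(any(grepl("toward the weak end", v)))
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(19)
  m <- build_symmetric_model(random_valid_params(6), 6)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$potentiation, m$potentiation)
  expect_identical(m2$depression, m$depression)
  expect_identical(m2$efficacies, m$efficacies)
  expect_identical(m2$n_states, m$n_states)
})
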