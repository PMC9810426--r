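test_that("island and per-population transmission matrices follow their closed forms", {
  A <- transmission_matrix(transmission_spec("island", n = 3, c = 0.2))
  expect_equal(unname(diag(A)), rep(0.8, 3))
  expect_equal(A[1, 2], 0.1)
  expect_equal(A[3, 1], 0.1)

  A0 <- transmission_matrix(transmission_spec("island", n = 4, c = 0))
  expect_equal(unclass(A0), diag(4), ignore_attr = TRUE)

  App <- transmission_matrix(
    transmission_spec("per_population", c = c(0.1, 0.4, 0.9)))
  expect_equal(diag(App), c(0.9, 0.6, 0.1))
  expect_equal(App[2, 1], 0.2)
  expect_equal(rowSums(App), rep(1, 3))
})

test_that("grid transmission handles boundary degrees and the d bound", {
  A <- transmission_matrix(transmission_spec("grid", L = 2, d = 0.15))
  # every square of a 2x2 grid has two neighbours
  expect_equal(unname(diag(A)), rep(0.7, 4))
  expect_equal(sum(A[1, ] == 0.15), 2)
  expect_equal(rowSums(A), rep(1, 4))

  A3 <- transmission_matrix(transmission_spec("grid", L = 3, d = 0.2))
  # corner degree 2, edge degree 3, centre degree 4
  expect_equal(A3[1, 1], 1 - 0.2 * 2)
  expect_equal(A3[2, 2], 1 - 0.2 * 3)
  expect_equal(A3[5, 5], 1 - 0.2 * 4)
  # zero off the lattice edges
  expect_equal(A3[1, 9], 0)
  expect_error(transmission_spec("grid", L = 3, d = 0.3), "d <= 0.25")
  expect_error(transmission_spec("island", n = 3, c = 1.2), "\\[0, 1\\]")
})

test_that("gravity rows are normalized and favour large nearby populations", {
  set.seed(1)
  coords <- data.frame(x = runif(5), y = runif(5))
  sp <- transmission_spec("gravity", sigma = 0.5,
                          sizes = c(5, 1, 1, 1, 10), coords = coords)
  A <- transmission_matrix(sp)
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
  expect_true(all(A > 0))
})

test_that("mutation matrices follow their closed forms and validate input", {
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
  expect_equal(unclass_m(Q), rbind(c(0.96, 0.04), c(0.08, 0.92)))

  Q0 <- mutation_matrix(mutation_spec("uniform", k = 2, mu = 0))
  expect_equal(unclass_m(Q0), diag(2))

  Q3 <- mutation_matrix(mutation_spec("uniform", k = 3, mu = 0.06))
  expect_equal(unname(diag(Q3)), rep(0.94, 3))
  expect_equal(Q3[1, 2], 0.03)

  bad <- rbind(c(0.9, 0.2), c(0.1, 0.9))
  expect_error(mutation_spec("explicit", matrix = bad), "sum to 1")
  expect_error(mutation_spec("two_state", q12 = -0.1, q21 = 0.5), "\\[0, 1\\]")
})

test_that("closed-form two-state powers equal naive products", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    q12 <- runif(1)
    q21 <- runif(1)
    Q <- mutation_matrix(mutation_spec("two_state", q12 = q12, q21 = q21))
    M <- unclass_m(Q)
    for (t in c(1:10, 25, 50)) {
      err <- max(abs(matrix_power(Q, t) - naive_power(M, t)))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("matrix powers handle t = 0, long horizons and caching", {
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
  expect_equal(matrix_power(Q, 0), diag(2))
  P <- matrix_power(Q, 10000)
  expect_equal(P[1, ], c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(P[2, ], c(2, 1) / 3, tolerance = 1e-12)
  # generic family: repeated squaring, cached per t
  set.seed(7)
  M <- random_stochastic(3)
  Qg <- mutation_matrix(mutation_spec("explicit", matrix = M))
  expect_equal(matrix_power(Qg, 7), naive_power(M, 7), tolerance = 1e-12)
  expect_identical(matrix_power(Qg, 7), matrix_power(Qg, 7))
})

test_that("stationary distributions match eigen decomposition and power limits", {
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
  expect_equal(stationary_distribution(Q), c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(stationary_distribution(Q), matrix_power(Q, 1e6)[1, ],
               tolerance = 1e-8)

  Qu <- mutation_matrix(mutation_spec("uniform", k = 4, mu = 0.2))
  expect_equal(stationary_distribution(Qu), rep(0.25, 4))

  set.seed(11)
  for (i in 1:5) {
    M <- random_stochastic(3)
    Qg <- mutation_matrix(mutation_spec("explicit", matrix = M))
    pi <- stationary_distribution(Qg)
    expect_lt(max(abs(pi %*% M - pi)), 1e-12)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }

  Qabs <- mutation_matrix(mutation_spec("two_state", q12 = 0, q21 = 0))
  expect_error(stationary_distribution(Qabs), "stationary prior undefined")
  Qred <- mutation_matrix(mutation_spec("explicit", matrix = diag(3)))
  expect_error(stationary_distribution(Qred), "stationary prior undefined")
})

test_that("row stochasticity holds across families and random parameters", {
  set.seed(3)
  for (i in 1:20) {
    specs <- list(
      transmission_spec("island", n = sample(2:8, 1), c = runif(1)),
      transmission_spec("grid", L = sample(2:5, 1), d = runif(1, 0, 0.25)),
      transmission_spec("per_population", c = runif(sample(2:6, 1)))
    )
    for (sp in specs)
      expect_lt(max(abs(rowSums(transmission_matrix(sp)) - 1)), 1e-12)
    Q <- mutation_matrix(mutation_spec("two_state", q12 = runif(1),
                                       q21 = runif(1)))
    expect_lt(max(abs(rowSums(unclass_m(Q)) - 1)), 1e-12)
  }
})
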