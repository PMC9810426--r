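two_leaf_tree <- function(t1, t2, pops = c(1L, 2L), root_pop = 3L) {
  genealogy(parent = c(3L, 3L, NA), age = c(0L, 0L, max(t1, t2)),
            population = c(pops, root_pop), leaves = pops)
}

test_that("pruning handles exact degenerate cases", {
  Qid <- mutation_matrix(mutation_spec("uniform", k = 2, mu = 0))
  tr <- two_leaf_tree(2, 2)
  expect_equal(pruning_likelihood(tr, Qid, c(1, 1), S = 1), 1)
  expect_equal(pruning_likelihood(tr, Qid, c(1, 2), S = 1), 0)
  expect_equal(pruning_likelihood(tr, Qid, c(2, 2), S = 1), 0)
})

test_that("two-leaf likelihood equals the product of transition entries", {
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.07, q21 = 0.19))
  # unequal leaf ages are not possible in a traced genealogy, but the
  # recursion only uses branch lengths; build branch lengths via root age
  for (t in c(1, 3, 17)) {
    tr <- two_leaf_tree(t, t)
    P <- matrix_power(Q, t)
    for (S in 1:2) for (j1 in 1:2) for (j2 in 1:2)
      expect_equal(pruning_likelihood(tr, Q, c(j1, j2), S),
                   P[S, j1] * P[S, j2], tolerance = 1e-14)
  }
})

test_that("pruning equals brute-force summation on random small trees", {
  set.seed(21)
  A <- transmission_matrix(transmission_spec("island", n = 6, c = 0.5))
  worst <- 0
  for (rep in 1:40) {
    m <- sample(2:4, 1)
    k <- sample(2:3, 1)
    tr <- NULL
    while (is.null(tr)) tr <- sample_prior_tree(A, sample.int(6, m), 200)
    Q <- mutation_matrix(mutation_spec("explicit",
                                       matrix = random_stochastic(k)))
    ls <- sample.int(k, m, replace = TRUE)
    for (S in seq_len(k)) {
      a <- pruning_likelihood(tr, Q, ls, S)
      b <- brute_likelihood(tr, Q, ls, S)
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("likelihoods over all leaf assignments sum to one", {
  set.seed(22)
  A <- transmission_matrix(transmission_spec("island", n = 5, c = 0.6))
  for (rep in 1:10) {
    m <- sample(2:4, 1)
    k <- sample(2:3, 1)
    tr <- NULL
    while (is.null(tr)) tr <- sample_prior_tree(A, sample.int(5, m), 200)
    Q <- mutation_matrix(mutation_spec("explicit",
                                       matrix = random_stochastic(k)))
    S <- sample.int(k, 1)
    combs <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
    tot <- sum(apply(combs, 1, function(ls)
      pruning_likelihood(tr, Q, as.integer(ls), S)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("root marginal equals the prior-weighted sum over root states", {
  set.seed(23)
  A <- transmission_matrix(transmission_spec("island", n = 5, c = 0.6))
  tr <- NULL
  while (is.null(tr)) tr <- sample_prior_tree(A, c(1, 2, 4), 200)
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.1, q21 = 0.25))
  pi <- stationary_distribution(Q)
  ls <- c(1, 2, 1)
  direct <- sum(vapply(1:2, function(S)
    pi[S] * pruning_likelihood(tr, Q, ls, S), numeric(1)))
  expect_equal(root_marginal_likelihood(tr, Q, ls), direct, tolerance = 1e-14)

  # identity mutation, all leaves in state 1: only root state 1 survives
  Qid <- mutation_matrix(mutation_spec("uniform", k = 2, mu = 0,
                                       root_prior = c(0.7, 0.3)))
  expect_equal(root_marginal_likelihood(tr, Qid, c(1, 1, 1)), 0.7)

  # single-leaf genealogy: marginal likelihood is the root prior mass
  t1 <- genealogy(NA_integer_, 0L, 2L, 2L)
  expect_equal(root_marginal_likelihood(t1, Qid, 2), 0.3)
})

test_that("the closed-form fast path matches the generic pruning on long branches", {
  q12 <- 3e-4; q21 <- 7e-4
  Qf <- mutation_matrix(mutation_spec("two_state", q12 = q12, q21 = q21))
  Qe <- mutation_matrix(mutation_spec(
    "explicit", matrix = rbind(c(1 - q12, q12), c(q21, 1 - q21))))
  tr <- genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                  age = c(0L, 0L, 0L, 3000L, 10000L),
                  population = c(1L, 2L, 3L, 1L, 2L),
                  leaves = c(1L, 2L, 3L))
  for (S in 1:2) for (j in list(c(1, 1, 2), c(2, 2, 2), c(1, 2, 1)))
    expect_equal(pruning_likelihood(tr, Qf, j, S),
                 pruning_likelihood(tr, Qe, j, S), tolerance = 1e-10)
})

test_that("leaf-state validation catches unassigned and mismatched states", {
  tr <- two_leaf_tree(2, 2)
  Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.1, q21 = 0.1))
  expect_error(pruning_likelihood(tr, Q, c(1), 1), "each of the 2 leaves")
  expect_error(pruning_likelihood(tr, Q, c(1, 3), 1), "1..k")
  named <- c(`2` = 1, `9` = 2)
  expect_error(pruning_likelihood(tr, Q, named, 1), "assigned state")
})
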