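make_two_topologies <- function() {
  # ((1,2),3) with ages 1, 2  and  (1,(2,3)) with ages 1, 2
  t1 <- genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                  age = c(0L, 0L, 0L, 1L, 2L),
                  population = c(1L, 2L, 3L, 7L, 8L),
                  leaves = c(1L, 2L, 3L))
  t2 <- genealogy(parent = c(5L, 4L, 4L, 5L, NA),
                  age = c(0L, 0L, 0L, 1L, 2L),
                  population = c(1L, 2L, 3L, 7L, 8L),
                  leaves = c(1L, 2L, 3L))
  list(t1 = t1, t2 = t2)
}

test_that("clade frequencies count leaf sets correctly", {
  tt <- make_two_topologies()
  same <- rep(list(tt$t1), 10)
  cf <- clade_frequencies(same)
  expect_true(all(cf$frequency == 1))

  mix <- c(rep(list(tt$t1), 6), rep(list(tt$t2), 4))
  cf <- clade_frequencies(mix)
  expect_equal(cf$frequency[cf$clade == "1,2"], 0.6)
  expect_equal(cf$frequency[cf$clade == "2,3"], 0.4)
  expect_equal(cf$frequency[cf$clade == "1,2,3"], 1)
  expect_true(all(cf$frequency[cf$size == 1] == 1))

  t_bad <- genealogy(parent = c(3L, 3L, NA), age = c(0L, 0L, 1L),
                     population = c(1L, 4L, 2L), leaves = c(1L, 4L))
  expect_error(clade_frequencies(list(tt$t1, t_bad)), "same leaf label set")
  expect_error(clade_frequencies(list()), "empty")
})

test_that("clade frequencies match a naive per-tree counting oracle", {
  A <- transmission_matrix(transmission_spec("island", n = 6, c = 0.6))
  set.seed(51)
  trees <- list()
  while (length(trees) < 100) {
    tr <- sample_prior_tree(A, c(1, 3, 5, 6), 500)
    if (!is.null(tr)) trees[[length(trees) + 1]] <- tr
  }
  cf <- clade_frequencies(trees)
  # oracle: count sets directly
  all_keys <- unlist(lapply(trees, tree_clade_keys))
  for (i in seq_len(nrow(cf)))
    expect_equal(cf$frequency[i],
                 sum(all_keys == cf$clade[i]) / length(trees))
})

test_that("the MCC tree maximizes clade support and annotates nodes", {
  tt <- make_two_topologies()
  single <- mcc_tree(list(tt$t1))
  expect_true(all(single$support == 1))

  mix <- c(rep(list(tt$t1), 6), rep(list(tt$t2), 4))
  mcc <- mcc_tree(mix)
  expect_true("1,2" %in% tree_clade_keys(mcc))    # majority topology wins
  expect_equal(sort(mcc$support), sort(c(1, 1, 1, 0.6, 1)))
  # order invariance (supports identical, same topology)
  mcc_rev <- mcc_tree(rev(mix))
  expect_equal(sort(tree_clade_keys(mcc)), sort(tree_clade_keys(mcc_rev)))
  expect_error(mcc_tree(list()), "empty")
})

test_that("MCC selection agrees with an independent implementation", {
  A <- transmission_matrix(transmission_spec("grid", L = 4, d = 0.15))
  set.seed(52)
  trees <- list()
  while (length(trees) < 1000) {
    tr <- sample_prior_tree(A, c(1, 4, 6, 11, 13, 16), 2000)
    if (!is.null(tr)) trees[[length(trees) + 1]] <- tr
  }
  mcc <- mcc_tree(trees)
  phys <- lapply(trees, as_phylo)
  class(phys) <- "multiPhylo"
  ref <- phangorn::maxCladeCred(phys, rooted = TRUE)
  expect_equal(
    ape::dist.topo(ape::unroot(as_phylo(mcc)), ape::unroot(ref)), 0,
    ignore_attr = TRUE)
})

test_that("clade state concordance distinguishes sorted from mixed trees", {
  tt <- make_two_topologies()
  states <- c(`1` = 1L, `2` = 1L, `3` = 2L)
  # t1 groups the two state-1 leaves; t2 groups a mixed pair
  expect_equal(clade_state_concordance(list(tt$t1), states), 1)
  expect_equal(clade_state_concordance(list(tt$t2), states), 0)
  expect_equal(clade_state_concordance(list(tt$t1, tt$t2), states), 0.5)
})

test_that("state maps combine observations and marginals and round-trip", {
  obs <- simulate_grid_dataset(L = 3, generations = 100, n_infer = 2,
                               seed = 53)
  # no marginals: observed cells carry their datum, targets are NA
  map0 <- state_map(obs)
  expect_equal(nrow(map0), 9)
  oi <- map0$status == "observed"
  expect_true(all(map0$p_state_1[oi] %in% c(0, 1)))
  expect_true(all(is.na(map0$p_state_1[map0$status == "infer"])))

  marg <- tibble::tibble(
    population = rep(obs$infer, each = 2),
    state = rep(1:2, length(obs$infer)),
    probability = rep(c(0.25, 0.75), length(obs$infer)))
  map <- state_map(obs, marg)
  expect_equal(map$p_state_1[map$status == "infer"],
               rep(0.25, length(obs$infer)))
  rs <- rowSums(map[!is.na(map$p_state_1), c("p_state_1", "p_state_2")])
  expect_true(all(abs(rs - 1) < 1e-12))

  # dataset round trip preserves the observation structure behind the map
  f <- tempfile(fileext = ".tsv")
  write_dataset(obs, f)
  obs2 <- read_dataset(f)
  expect_identical(obs$observed, obs2$observed)
  expect_identical(obs$infer, obs2$infer)
  map2 <- state_map(obs2, marg)
  expect_equal(map$p_state_1, map2$p_state_1)
})
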