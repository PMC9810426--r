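test_that("effective sample size behaves on white noise, AR(1) and constants", {
  set.seed(41)
  x <- stats::rnorm(10000)
  ess <- effective_sample_size(x)
  expect_gt(ess, 8000)
  expect_lte(ess, 12000)

  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n = 20000))
  target <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - target) / target, 0.25)

  expect_warning(ess_c <- effective_sample_size(rep(1, 500)), "constant")
  expect_true(is.na(ess_c))
  expect_error(effective_sample_size(stats::rnorm(50)), "at least 100")
})

test_that("posterior state marginals match direct counting", {
  ti <- tiny_instance()
  cfg <- mcmc_config(iterations = 3000, burnin = 500, thin = 1, seed = 42,
                     tree_thin = 100)
  fit <- run_mcmc_exact(ti$obs, ti$tspec, ti$mspec, ti$priors, cfg,
                        tau = ti$tau)
  marg <- posterior_state_marginals(fit)
  hand <- c(mean(fit$draws$x_3 == 1L), mean(fit$draws$x_3 == 2L))
  expect_equal(marg$probability, hand)
  expect_equal(sum(marg$probability), 1)
  expect_error(posterior_state_marginals(fit, populations = 1),
               "not inference-target")
})

test_that("zero-information data return the prior for mutation rates", {
  # one observed population, uniform root prior: the likelihood is 1/k for
  # every parameter value, so the mutation-rate posterior is its U prior
  obs <- observation_set(n = 3, k = 2, observed = c(`1` = 1L))
  priors <- prior_config(
    theta_tau = list(c = prior_fixed(0.5)),
    theta_mu = list(q12 = prior_uniform(0, 0.1),
                    q21 = prior_uniform(0, 0.1)))
  cfg <- mcmc_config(iterations = 30000, burnin = 3000, thin = 1, seed = 43,
                     tree_thin = 1000,
                     steps = list(q12 = 0.04, q21 = 0.04))
  fit <- run_mcmc_exact(
    obs,
    function(p) transmission_spec("island", n = 3, c = p$c),
    function(p) mutation_spec("two_state", q12 = p$q12, q21 = p$q21,
                              root_prior = "uniform"),
    priors, cfg, tau = 3)
  for (nm in c("q12", "q21")) {
    v <- fit$draws[[nm]]
    ess <- effective_sample_size(v)
    expect_lt(abs(mean(v) - 0.05), 3 * 0.1 / sqrt(12) / sqrt(ess))
    # sampling error of the variance is about sigma^2 * sqrt(2 / ess)
    expect_lt(abs(stats::var(v) - 0.1^2 / 12) / (0.1^2 / 12),
              3 * sqrt(2 / ess))
  }
})

test_that("recorded likelihood components are reproducible from the state", {
  ti <- tiny_instance()
  cfg <- mcmc_config(iterations = 500, burnin = 100, thin = 1, seed = 44,
                     tree_thin = 1L)
  fit <- run_mcmc_exact(ti$obs, ti$tspec, ti$mspec, ti$priors, cfg,
                        tau = ti$tau)
  trees <- fit$trees
  rp <- root_state_prior(ti$Q)
  for (i in seq_len(nrow(fit$draws))) {
    d <- fit$draws[i, ]
    lp <- cultree:::root_log_partials(
      trees[[i]], ti$Q,
      stats::setNames(c(1L, 2L, d$x_3), c(1L, 2L, 3L)))
    expect_equal(d$log_likelihood, lp[d$s_root], tolerance = 1e-9)
    expect_equal(d$log_root_prior, log(rp[d$s_root]), tolerance = 1e-9)
    expect_equal(d$tmrca, tmrca(trees[[i]]))
  }
})

test_that("the stationary chain is balanced between ancestral-state bins", {
  ti <- tiny_instance()
  cfg <- mcmc_config(iterations = 40000, burnin = 5000, thin = 1, seed = 45,
                     tree_thin = 5000)
  fit <- run_mcmc_exact(ti$obs, ti$tspec, ti$mspec, ti$priors, cfg,
                        tau = ti$tau)
  s <- fit$draws$s_root
  n12 <- sum(s[-length(s)] == 1L & s[-1] == 2L)
  n21 <- sum(s[-length(s)] == 2L & s[-1] == 1L)
  expect_lt(abs(n12 - n21), 3 * sqrt(n12 + n21))
})

test_that("a single-tree pool pins the genealogy and the sampler still runs", {
  ti <- tiny_instance()
  A <- ti$A
  set.seed(46)
  tr <- NULL
  while (is.null(tr)) tr <- sample_prior_tree(A, c(1, 2, 3), 3)
  pool <- structure(list(trees = rep(list(tr), 50),
                         theta = tibble::tibble(c = rep(0.3, 50)),
                         leaves = c(1L, 2L, 3L), tau_max = 3L,
                         attempted = 50L),
                    class = "prior_tree_pool")
  cfg <- mcmc_config(iterations = 2000, burnin = 200, thin = 1, seed = 47)
  expect_warning(
    fit <- run_mcmc_heuristic(ti$obs, pool, ti$mspec, ti$priors, cfg),
    "very small")
  expect_true(all(fit$draws$tmrca == tmrca(tr)))
  expect_true(all(fit$draws$mrca_population == mrca_population(tr)))

  # leaf-set mismatch is rejected up front
  obs_bad <- observation_set(n = 3, k = 2, observed = c(`1` = 1L, `2` = 2L))
  expect_error(run_mcmc_heuristic(obs_bad, pool, ti$mspec, ti$priors, cfg),
               "leaf set")
})

test_that("state-symmetric problems give exchangeable marginals", {
  # q12 = q21 and mirrored observations: relabelling the two states maps
  # the problem onto itself, so P(X = 1 | data) + P(X = 1 | relabelled
  # data) must equal 1 up to Monte-Carlo error
  priors <- prior_config(
    theta_tau = list(c = prior_fixed(0.4)),
    theta_mu = list(q12 = prior_fixed(0.15), q21 = prior_fixed(0.15)))
  tspec <- function(p) transmission_spec("island", n = 4, c = p$c)
  mspec <- function(p) mutation_spec("two_state", q12 = p$q12, q21 = p$q21)
  run_one <- function(states, seed) {
    obs <- observation_set(n = 4, k = 2,
                           observed = stats::setNames(states, 1:3), infer = 4L)
    cfg <- mcmc_config(iterations = 40000, burnin = 5000, thin = 1,
                       seed = seed, tree_thin = 5000)
    fit <- run_mcmc_exact(obs, tspec, mspec, priors, cfg, tau = 6)
    posterior_state_marginals(fit)$probability[1]
  }
  p1 <- run_one(c(1L, 1L, 2L), 48)
  p2 <- run_one(c(2L, 2L, 1L), 49)
  expect_lt(abs(p1 + p2 - 1), 0.03)
})

test_that("tidy and glance summarize a fit", {
  ti <- tiny_instance()
  priors <- prior_config(
    theta_tau = list(c = prior_fixed(0.3)),
    theta_mu = list(q12 = prior_uniform(0, 0.3), q21 = prior_uniform(0, 0.3)))
  cfg <- mcmc_config(iterations = 4000, burnin = 400, thin = 1, seed = 50,
                     tree_thin = 500)
  fit <- run_mcmc_exact(ti$obs, ti$tspec, ti$mspec, priors, cfg, tau = ti$tau)
  td <- tidy(fit)
  expect_setequal(td$term, c("q12", "q21", "tmrca"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$retained, nrow(fit$draws))
  expect_equal(gl$algorithm, "exact_G")
  expect_true(gl$acceptance_rate > 0 && gl$acceptance_rate <= 1)
})
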