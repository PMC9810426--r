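#' Simulate a grid dataset
#'
#' Forward-simulates the two-state dynamics on an `L` by `L` grid and
#' masks part of the final generation, producing an [observation_set()]
#' ready for inference.  Defaults mirror the package's standard simulation
#' study: neighbour transmission rate `d = 0.15` and asymmetric mutation.
#'
#' @param L Grid side length.
#' @param d Neighbour transmission rate.
#' @param q12,q21 Mutation rates.
#' @param generations Forward generations simulated from a uniform-random
#'   start (default `1e4`, ample for these mixing times: the mutation
#'   process alone mixes in roughly `1/(q12+q21)` generations).
#' @param observed Population indices to observe; `NULL` observes all
#'   populations that are not inference targets.
#' @param infer Population indices to hide as inference targets.
#' @param n_infer Alternatively, a count of targets drawn at random.
#' @param seed Integer seed.
#' @return An [observation_set()] with grid layout and the full truth kept
#'   in field `truth` for benchmarking.
#' @export
simulate_grid_dataset <- function(L, d = 0.15, q12 = 0.04, q21 = 0.08,
                                  generations = 1e4, observed = NULL,
                                  infer = integer(0), n_infer = 0, seed) {
  A <- transmission_matrix(transmission_spec("grid", L = L, d = d))
  Q <- mutation_matrix(mutation_spec("two_state", q12 = q12, q21 = q21))
  n <- L^2
  set.seed(seed)
  init <- sample.int(2L, n, replace = TRUE)
  states <- simulate_forward(A, Q, generations = generations, init = init)
  # target selection continues the same seeded stream
  infer_idx <- sort(as.integer(infer))
  if (n_infer > 0) {
    if (length(infer_idx)) stop("give either `infer` or `n_infer`, not both")
    infer_idx <- sort(sample.int(n, n_infer))
  }
  observed_idx <- if (is.null(observed)) setdiff(seq_len(n), infer_idx)
                  else sort(as.integer(observed))
  mask_dataset(states, observed_idx, infer_idx, k = 2,
               layout = grid_layout(L))
}

#' Mutation-rate recovery study on a grid
#'
#' Replicated parameter-recovery experiment: datasets are simulated on an
#' `L` by `L` grid with known rates, the exact history sampler is run with
#' the transmission rate held fixed (its documented default on grids) and
#' uniform `U(0, 0.1)` priors on both mutation rates, and each replicate
#' records whether the true rates fall inside the central 95% credible
#' intervals.
#'
#' @param n_replicates Number of replicate datasets.
#' @param L Grid side (default 6).
#' @param d,q12,q21 True simulation parameters.
#' @param m,l Observed and inference-target counts per dataset.
#' @param tau History depth for inference (default 600 generations, a
#'   comfortable bound: backward coalescence of all lineages on this grid
#'   typically completes within a couple hundred generations).
#' @param iterations,burnin,thin Chain settings per replicate.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param conf_level Credible-interval mass (default 0.95).
#' @return Tibble with one row per replicate: interval bounds, posterior
#'   means and coverage indicators for `q12` and `q21`.
#' @export
recovery_experiment <- function(n_replicates = 20, L = 6, d = 0.15,
                                q12 = 0.04, q21 = 0.08, m = 30, l = 6,
                                tau = 600, iterations = 20000,
                                burnin = NULL, thin = 2, seed = 1,
                                conf_level = 0.95) {
  n <- L^2
  stopifnot(m + l <= n)
  priors <- prior_config(
    theta_tau = list(d = prior_fixed(d)),
    theta_mu = list(q12 = prior_uniform(0, 0.1), q21 = prior_uniform(0, 0.1))
  )
  tspec <- function(p) transmission_spec("grid", L = L, d = p$d)
  mspec <- function(p) mutation_spec("two_state", q12 = p$q12, q21 = p$q21)
  rows <- lapply(seq_len(n_replicates), function(r) {
    rs <- seed + r
    obs <- simulate_grid_dataset(L, d, q12, q21, observed = NULL,
                                 n_infer = l, seed = rs)
    # drop extra observed populations down to m (keeping targets)
    set.seed(rs + 500000L)
    oi <- as.integer(names(obs$observed))
    keep <- sort(sample(oi, m))
    obs2 <- observation_set(n, 2L,
                            stats::setNames(obs$observed[as.character(keep)], keep),
                            infer = obs$infer, layout = obs$layout)
    cfg <- mcmc_config(iterations = iterations, burnin = burnin, thin = thin,
                       seed = rs + 1000000L, tree_thin = 50L)
    fit <- run_mcmc_exact(obs2, tspec, mspec, priors, cfg, tau = tau)
    td <- tidy(fit, conf_level = conf_level)
    r12 <- td[td$term == "q12", ]; r21 <- td[td$term == "q21", ]
    tibble::tibble(
      replicate = r,
      q12_mean = r12$estimate, q12_low = r12$conf.low, q12_high = r12$conf.high,
      q12_covered = r12$conf.low <= q12 & q12 <= r12$conf.high,
      q21_mean = r21$estimate, q21_low = r21$conf.low, q21_high = r21$conf.high,
      q21_covered = r21$conf.low <= q21 & q21 <= r21$conf.high
    )
  })
  dplyr::bind_rows(rows)
}

#' Genealogy reconstruction study on a small grid
#'
#' Joint inference of the transmission rate, mutation rates and the
#' genealogy of six focal state copies on a 4 by 4 grid, with the
#' heuristic pool sampler.  The dataset is forward-simulated; simulation
#' repeats (bumping the seed) until the six focal populations carry both
#' states, so the prior-versus-posterior clade comparison is defined.
#'
#' @param L Grid side (default 4, all populations observed).
#' @param focal Population indices of the six traced copies (default: the
#'   four corners plus two interior squares, spread over the grid).
#' @param d,q12,q21 True simulation parameters.
#' @param generations Forward simulation length.
#' @param pool_size Prior trees sampled (default `1e5`).
#' @param tau_max Coalescent truncation horizon (default 2000
#'   generations; six lineages on this grid typically coalesce within a
#'   few hundred).
#' @param iterations,burnin,thin Chain settings.
#' @param seed Base seed.
#' @return List with elements `obs`, `pool`, `fit`, and `stats` — a
#'   one-row tibble comparing prior and posterior mean TMRCA and clade
#'   state concordance.
#' @export
genealogy_experiment <- function(L = 4, focal = c(1, 4, 6, 11, 13, 16),
                                 d = 0.15, q12 = 0.01, q21 = 0.02,
                                 generations = 1e4, pool_size = 1e5,
                                 tau_max = 2000, iterations = 30000,
                                 burnin = NULL, thin = 2, seed = 1) {
  n <- L^2
  priors <- prior_config(
    theta_tau = list(d = prior_uniform(0.1, 0.2)),
    theta_mu = list(q12 = prior_uniform(0, 0.03),
                    q21 = prior_uniform(0, 0.03))
  )
  # simulate until the focal copies show both states
  obs <- NULL
  for (bump in 0:99) {
    cand <- simulate_grid_dataset(L, d, q12, q21, generations = generations,
                                  observed = focal, infer = integer(0),
                                  seed = seed + 7919L * bump)
    if (length(unique(unname(cand$observed))) > 1L) { obs <- cand; break }
  }
  if (is.null(obs)) stop("focal states were monomorphic in 100 simulations")

  pool <- build_prior_pool(
    function(p) transmission_spec("grid", L = L, d = p$d),
    priors, leaves = focal, pool_size = pool_size, tau_max = tau_max,
    seed = seed + 1L)
  cfg <- mcmc_config(iterations = iterations, burnin = burnin, thin = thin,
                     seed = seed + 2L)
  fit <- run_mcmc_heuristic(obs, pool,
    function(p) mutation_spec("two_state", q12 = p$q12, q21 = p$q21),
    priors, cfg)

  states <- stats::setNames(unname(obs$observed), names(obs$observed))
  post_trees <- sampled_trees(fit)
  prior_tmrca <- mean(vapply(pool$trees, tmrca, numeric(1)))
  post_tmrca <- mean(fit$draws$tmrca)
  # concordance on a prior subsample matching the posterior sample size
  sub <- pool$trees[seq(1, length(pool$trees),
                        length.out = min(length(post_trees), length(pool$trees)))]
  stats <- tibble::tibble(
    prior_mean_tmrca = prior_tmrca,
    posterior_mean_tmrca = post_tmrca,
    prior_concordance = clade_state_concordance(sub, states),
    posterior_concordance = clade_state_concordance(post_trees, states)
  )
  list(obs = obs, pool = pool, fit = fit, stats = stats)
}

#' The three-population benchmark instance
#'
#' A complete-graph (island) network of three populations, two observed
#' states and one inference target, small enough for the posterior to be
#' computed exactly by [enumerate_posterior()] — the package's primary
#' correctness benchmark for both samplers.
#'
#' @param c Island transmission rate (default 0.3).
#' @param q12,q21 Fixed mutation rates (defaults 0.1 and 0.2, moderate so
#'   that all posterior marginals stay away from 0 and 1).
#' @param tau History depth (default 3).
#' @return List with `obs`, `A`, `Q`, `tau`, `tspec`, `mspec`, `priors`.
#' @export
tiny_instance <- function(c = 0.3, q12 = 0.1, q21 = 0.2, tau = 3) {
  obs <- observation_set(n = 3, k = 2,
                         observed = c(`1` = 1L, `2` = 2L), infer = 3L)
  A <- transmission_matrix(transmission_spec("island", n = 3, c = c))
  Q <- mutation_matrix(mutation_spec("two_state", q12 = q12, q21 = q21))
  priors <- prior_config(
    theta_tau = list(c = prior_fixed(c)),
    theta_mu = list(q12 = prior_fixed(q12), q21 = prior_fixed(q21))
  )
  list(obs = obs, A = A, Q = Q, tau = tau,
       tspec = function(p) transmission_spec("island", n = 3, c = p$c),
       mspec = function(p) mutation_spec("two_state", q12 = p$q12,
                                         q21 = p$q21),
       priors = priors)
}
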