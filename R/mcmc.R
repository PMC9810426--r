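#' Exact posterior sampling over the transmission history
#'
#' Metropolis–Hastings sampler for the joint posterior of the transmission
#' parameters, mutation parameters, latent history matrix `G`, ancestral
#' state `S` and unknown present-day states `X`, proportional to
#' `P(D, X | theta_mu, G, S) P(S | theta_mu) P(G | theta_tau) P(theta_tau)
#' P(theta_mu)`.  The data `D` are the observed states together with the
#' prior constraint that all traced lineages coalesce within `tau`
#' generations; any history whose lineages fail to do so has zero
#' posterior probability.
#'
#' Moves (random-scan, weighted):
#' * `g_entry` — one entry of `G`, proposed from the matching row of `A`
#'   (prior-informed independence proposal, so the acceptance ratio is the
#'   likelihood ratio; entries off the traced lineages are accepted by the
#'   prior alone).
#' * `g_column` — one whole column of `G` redrawn from its prior.
#' * `g_resim` — the whole matrix redrawn from its prior conditioned on
#'   coalescence; the conditioning constant cancels between proposal and
#'   target, leaving a likelihood-ratio acceptance.
#' * `theta_tau`, `theta_mu` — reflected uniform random walks within the
#'   prior bounds, one component at a time.
#' * `s` — Gibbs draw of the ancestral state from the root partial
#'   likelihoods times the root prior.
#' * `x` — Gibbs draw of one unknown present-day state.
#'
#' @param obs An [observation_set()].
#' @param tspec A function mapping a named list of transmission-parameter
#'   values to a [transmission_spec()], or a fixed spec (in which case
#'   `priors$theta_tau` must be empty or fixed).
#' @param mspec As `tspec`, for the mutation model.
#' @param priors A [prior_config()].
#' @param config An [mcmc_config()].
#' @param tau Assumed upper bound on the MRCA age (rows of `G`).
#' @return A `"cultree_mcmc"` object; see [tidy.cultree_mcmc()],
#'   [posterior_state_marginals()], [sampled_trees()].
#' @seealso [run_mcmc_heuristic()], [enumerate_posterior()]
#' @export
run_mcmc_exact <- function(obs, tspec, mspec, priors, config, tau) {
  stopifnot(inherits(obs, "observation_set"), inherits(priors, "prior_config"),
            inherits(config, "mcmc_config"), tau >= 1)
  set.seed(config$seed)
  tau <- as.integer(tau)
  tspec_fn <- as_spec_fn(tspec, priors$theta_tau)
  mspec_fn <- as_spec_fn(mspec, priors$theta_mu)
  leaves <- leaf_populations(obs)
  m <- length(obs$observed); l <- length(obs$infer)
  n <- obs$n; k <- obs$k

  th_tau <- as.list(prior_means(priors$theta_tau))
  th_mu <- as.list(prior_means(priors$theta_mu))
  free_tau <- names(priors$theta_tau)[!vapply(priors$theta_tau, `[[`,
                                              logical(1), "fixed")]
  free_mu <- names(priors$theta_mu)[!vapply(priors$theta_mu, `[[`,
                                            logical(1), "fixed")]
  steps <- resolve_steps(config$steps, priors)

  A <- transmission_matrix(tspec_fn(th_tau))
  if (nrow(A) != n) stop("transmission model size does not match observation set")
  cumA <- row_cumprobs(A); logA <- log(A)
  Q <- mutation_matrix(mspec_fn(th_mu))
  if (attr(Q, "spec")$k != k) stop("mutation model k does not match observation set")
  rp <- root_state_prior(Q)

  # --- initial state ---------------------------------------------------------
  init <- NULL
  for (try in seq_len(config$init_retries)) {
    init <- propose_history(cumA, leaves, tau)
    if (!is.null(init)) break
  }
  if (is.null(init))
    stop("no coalescing initial history found within ", config$init_retries,
         " attempts: increase tau or strengthen transmission")
  G <- init$G; tree <- init$tree; occ <- init$occ
  counts <- transition_counts(history_matrix(G))
  lgp <- sum(counts[counts > 0] * logA[counts > 0])

  xs <- init_x_states(obs)
  lstates <- leaf_states(obs, xs)
  lp <- root_log_partials(tree, Q, lstates)
  S <- gibbs_root_state(lp, rp)
  ll <- lp[S]; lsp <- log(rp[S])
  if (!is.finite(ll + lsp))
    warning("initial state has zero likelihood; the chain may need a long burn-in")

  # --- move schedule ---------------------------------------------------------
  defaults <- c(g_entry = 0.5, g_column = 0.05, g_resim = 0.1,
                theta_tau = 0.1, theta_mu = 0.15, s = 0.05, x = 0.05)
  w <- resolve_weights(config$weights, defaults)
  if (length(free_tau) == 0) w["theta_tau"] <- 0
  if (length(free_mu) == 0) w["theta_mu"] <- 0
  if (l == 0) w["x"] <- 0
  if (all(w == 0)) stop("no applicable moves")
  moves <- sample(names(w), config$iterations, replace = TRUE, prob = w)

  sk <- trace_skeleton(config, c(names(th_tau), names(th_mu)), obs)
  rec_mat <- base::matrix(NA_real_, sk$nkeep, length(sk$cols),
                          dimnames = list(NULL, sk$cols))
  rec_trees <- vector("list", sk$nkeep)
  rec_row <- 0L
  lpr_theta <- log_prior_density(priors$theta_tau, th_tau) +
    log_prior_density(priors$theta_mu, th_mu)
  att <- acc <- stats::setNames(numeric(length(w)), names(w))

  for (it in seq_len(config$iterations)) {
    mv <- moves[it]
    att[mv] <- att[mv] + 1
    if (mv == "g_entry") {
      i <- sample.int(tau, 1L); j <- sample.int(n, 1L)
      new <- findInterval(stats::runif(1), cumA[j, ]) + 1L
      old <- G[i, j]
      if (new != old) {
        if (!occ[i, j]) {
          G[i, j] <- new
          counts[j, old] <- counts[j, old] - 1L
          counts[j, new] <- counts[j, new] + 1L
          lgp <- lgp + logA[j, new] - logA[j, old]
          acc[mv] <- acc[mv] + 1
        } else {
          G[i, j] <- new
          tri <- trace_lineages_int(G, leaves)
          ok <- FALSE
          if (!is.null(tri$tree)) {
            lp2 <- root_log_partials(tri$tree, Q, lstates)
            if (accept_log(lp2[S] - ll)) {
              tree <- tri$tree; occ <- occ_matrix(tri, tau, n)
              lp <- lp2; ll <- lp2[S]
              counts[j, old] <- counts[j, old] - 1L
              counts[j, new] <- counts[j, new] + 1L
              lgp <- lgp + logA[j, new] - logA[j, old]
              acc[mv] <- acc[mv] + 1; ok <- TRUE
            }
          }
          if (!ok) G[i, j] <- old
        }
      } else acc[mv] <- acc[mv] + 1
    } else if (mv == "g_column") {
      j <- sample.int(n, 1L)
      oldcol <- G[, j]
      newcol <- findInterval(stats::runif(tau), cumA[j, ]) + 1L
      G[, j] <- newcol
      if (!any(occ[, j])) {
        counts[j, ] <- tabulate(newcol, nbins = n)
        lgp <- lgp + sum(logA[j, newcol]) - sum(logA[j, oldcol])
        acc[mv] <- acc[mv] + 1
      } else {
        tri <- trace_lineages_int(G, leaves)
        ok <- FALSE
        if (!is.null(tri$tree)) {
          lp2 <- root_log_partials(tri$tree, Q, lstates)
          if (accept_log(lp2[S] - ll)) {
            tree <- tri$tree; occ <- occ_matrix(tri, tau, n)
            lp <- lp2; ll <- lp2[S]
            counts[j, ] <- tabulate(newcol, nbins = n)
            lgp <- lgp + sum(logA[j, newcol]) - sum(logA[j, oldcol])
            acc[mv] <- acc[mv] + 1; ok <- TRUE
          }
        }
        if (!ok) G[, j] <- oldcol
      }
    } else if (mv == "g_resim") {
      prop <- propose_history(cumA, leaves, tau)
      if (!is.null(prop)) {
        lp2 <- root_log_partials(prop$tree, Q, lstates)
        if (accept_log(lp2[S] - ll)) {
          G <- prop$G; tree <- prop$tree; occ <- prop$occ
          lp <- lp2; ll <- lp2[S]
          counts <- transition_counts(history_matrix(G))
          lgp <- sum(counts[counts > 0] * logA[counts > 0])
          acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mv == "theta_tau") {
      nm <- if (length(free_tau) == 1) free_tau else sample(free_tau, 1L)
      pr <- priors$theta_tau[[nm]]
      cand <- th_tau
      cand[[nm]] <- reflect_propose(th_tau[[nm]], steps[[nm]], pr$lo, pr$hi)
      A2 <- transmission_matrix(tspec_fn(cand))
      logA2 <- log(A2)
      used <- counts > 0
      lgp2 <- if (any(logA2[used] == -Inf)) -Inf
              else sum(counts[used] * logA2[used])
      if (accept_log(lgp2 - lgp)) {
        th_tau <- cand; A <- A2; logA <- logA2; lgp <- lgp2
        cumA <- row_cumprobs(A)
        acc[mv] <- acc[mv] + 1
      }
    } else if (mv == "theta_mu") {
      nm <- if (length(free_mu) == 1) free_mu else sample(free_mu, 1L)
      pr <- priors$theta_mu[[nm]]
      cand <- th_mu
      cand[[nm]] <- reflect_propose(th_mu[[nm]], steps[[nm]], pr$lo, pr$hi)
      Q2 <- mutation_matrix(mspec_fn(cand))
      rp2 <- root_state_prior(Q2)
      lp2 <- root_log_partials(tree, Q2, lstates)
      lsp2 <- log(rp2[S])
      if (accept_log((lp2[S] + lsp2) - (ll + lsp))) {
        th_mu <- cand; Q <- Q2; rp <- rp2; lp <- lp2
        ll <- lp2[S]; lsp <- lsp2
        acc[mv] <- acc[mv] + 1
      }
    } else if (mv == "s") {
      S <- gibbs_root_state(lp, rp)
      ll <- lp[S]; lsp <- log(rp[S])
      acc[mv] <- acc[mv] + 1
    } else if (mv == "x") {
      t1 <- if (l == 1) 1L else sample.int(l, 1L)
      res <- gibbs_x_state(tree, Q, lstates, m + t1, S, k)
      xs[t1] <- res$state
      lstates[m + t1] <- res$state
      lp <- res$lp; ll <- lp[S]
      acc[mv] <- acc[mv] + 1
    }

    if (sk$keep_set[it]) {
      rec_row <- rec_row + 1L
      rec_mat[rec_row, ] <- c(it, unlist(th_tau), unlist(th_mu), S, xs,
                              tmrca(tree), mrca_population(tree),
                              ll, lsp, lgp, lpr_theta,
                              ll + lsp + lgp + lpr_theta)
      if ((rec_row - 1L) %% config$tree_thin == 0L)
        rec_trees[[rec_row]] <- tree
    }
  }

  finish_mcmc(rec_mat, rec_trees, NULL, att, acc, config, obs, "exact_G",
              pool = NULL, priors = priors)
}

#' Heuristic posterior sampling over a prior tree pool
#'
#' Replaces the history-matrix prior by the empirical distribution of a
#' [build_prior_pool()] sample: the genealogy proposal draws a uniformly
#' random pool entry (whose generating transmission parameters ride
#' along), and because pool entries are i.i.d. prior draws the acceptance
#' ratio reduces to the likelihood ratio.  Mutation parameters, ancestral
#' state and unknown states move exactly as in [run_mcmc_exact()].  The
#' transmission-parameter posterior is read off the accepted entries'
#' attached draws.
#'
#' @inheritParams run_mcmc_exact
#' @param pool A [build_prior_pool()] result on the leaf set
#'   `observed + targets` of `obs`.
#' @return A `"cultree_mcmc"` object.
#' @export
run_mcmc_heuristic <- function(obs, pool, mspec, priors, config) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(pool, "prior_tree_pool"),
            inherits(config, "mcmc_config"))
  set.seed(config$seed)
  if (!setequal(pool$leaves, leaf_populations(obs)))
    stop("pool leaf set does not match the observation set's observed + target populations")
  npool <- length(pool$trees)
  if (npool < 100) warning("prior tree pool is very small (", npool,
                           " trees); posterior tree support will be coarse")
  mspec_fn <- as_spec_fn(mspec, priors$theta_mu)
  k <- obs$k
  l <- length(obs$infer)

  # leaf states in *pool* leaf order
  ord <- match(pool$leaves, leaf_populations(obs))
  m_pos <- which(!is.na(match(pool$leaves, as.integer(names(obs$observed)))))
  x_pos <- match(obs$infer, pool$leaves)

  th_mu <- as.list(prior_means(priors$theta_mu))
  free_mu <- names(priors$theta_mu)[!vapply(priors$theta_mu, `[[`,
                                            logical(1), "fixed")]
  steps <- resolve_steps(config$steps, priors)
  Q <- mutation_matrix(mspec_fn(th_mu))
  if (attr(Q, "spec")$k != k) stop("mutation model k does not match observation set")
  rp <- root_state_prior(Q)

  xs <- init_x_states(obs)
  full <- leaf_states(obs, xs)      # in obs leaf order
  lstates <- full[ord]              # reorder to pool leaf order

  idx <- sample.int(npool, 1L)
  tree <- pool$trees[[idx]]
  lp <- root_log_partials(tree, Q, lstates)
  S <- gibbs_root_state(lp, rp)
  ll <- lp[S]; lsp <- log(rp[S])

  defaults <- c(tree = 0.5, theta_mu = 0.3, s = 0.1, x = 0.1)
  w <- resolve_weights(config$weights, defaults)
  if (length(free_mu) == 0) w["theta_mu"] <- 0
  if (l == 0) w["x"] <- 0
  moves <- sample(names(w), config$iterations, replace = TRUE, prob = w)

  theta_names <- names(pool$theta)
  sk <- trace_skeleton(config, c(theta_names, names(th_mu)), obs)
  rec_mat <- base::matrix(NA_real_, sk$nkeep, length(sk$cols),
                          dimnames = list(NULL, sk$cols))
  rec_idx <- rep(NA_integer_, sk$nkeep)
  rec_row <- 0L
  theta_pool <- as.matrix(pool$theta)
  pool_tmrca <- vapply(pool$trees, tmrca, numeric(1))
  pool_mrca <- vapply(pool$trees, mrca_population, numeric(1))
  lpr_theta <- log_prior_density(priors$theta_mu, th_mu)
  att <- acc <- stats::setNames(numeric(length(w)), names(w))

  for (it in seq_len(config$iterations)) {
    mv <- moves[it]
    att[mv] <- att[mv] + 1
    if (mv == "tree") {
      idx2 <- sample.int(npool, 1L)
      tree2 <- pool$trees[[idx2]]
      lp2 <- root_log_partials(tree2, Q, lstates)
      if (accept_log(lp2[S] - ll)) {
        idx <- idx2; tree <- tree2; lp <- lp2; ll <- lp2[S]
        acc[mv] <- acc[mv] + 1
      }
    } else if (mv == "theta_mu") {
      nm <- if (length(free_mu) == 1) free_mu else sample(free_mu, 1L)
      pr <- priors$theta_mu[[nm]]
      cand <- th_mu
      cand[[nm]] <- reflect_propose(th_mu[[nm]], steps[[nm]], pr$lo, pr$hi)
      Q2 <- mutation_matrix(mspec_fn(cand))
      rp2 <- root_state_prior(Q2)
      lp2 <- root_log_partials(tree, Q2, lstates)
      lsp2 <- log(rp2[S])
      if (accept_log((lp2[S] + lsp2) - (ll + lsp))) {
        th_mu <- cand; Q <- Q2; rp <- rp2; lp <- lp2
        ll <- lp2[S]; lsp <- lsp2
        acc[mv] <- acc[mv] + 1
      }
    } else if (mv == "s") {
      S <- gibbs_root_state(lp, rp)
      ll <- lp[S]; lsp <- log(rp[S])
      acc[mv] <- acc[mv] + 1
    } else if (mv == "x") {
      t1 <- if (l == 1) 1L else sample.int(l, 1L)
      res <- gibbs_x_state(tree, Q, lstates, x_pos[t1], S, k)
      xs[t1] <- res$state
      lstates[x_pos[t1]] <- res$state
      lp <- res$lp; ll <- lp[S]
      acc[mv] <- acc[mv] + 1
    }

    if (sk$keep_set[it]) {
      rec_row <- rec_row + 1L
      rec_mat[rec_row, ] <- c(it, theta_pool[idx, ], unlist(th_mu), S, xs,
                              pool_tmrca[idx], pool_mrca[idx],
                              ll, lsp, NA_real_, lpr_theta,
                              ll + lsp + lpr_theta)
      rec_idx[rec_row] <- idx
    }
  }

  finish_mcmc(rec_mat, NULL, rec_idx, att, acc, config, obs, "heuristic_pool",
              pool = pool, priors = priors)
}

# ---- sampler internals -----------------------------------------------------

as_spec_fn <- function(spec, priors) {
  if (is.function(spec)) return(spec)
  if (inherits(spec, "transmission_spec") || inherits(spec, "mutation_spec")) {
    free <- names(priors)[!vapply(priors, `[[`, logical(1), "fixed")]
    if (length(free))
      stop("a fixed spec was given but priors leave ", toString(free),
           " free; pass a spec-building function instead")
    return(function(theta) spec)
  }
  stop("spec must be a spec object or a function(theta) returning one")
}

resolve_steps <- function(steps, priors) {
  all_priors <- c(priors$theta_tau, priors$theta_mu)
  out <- lapply(all_priors, function(p) (p$hi - p$lo) / 10)
  if (!is.null(steps)) out[names(steps)] <- steps
  out
}

resolve_weights <- function(weights, defaults) {
  w <- defaults
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), names(defaults))
    if (length(unknown)) stop("unknown move weights: ", toString(unknown))
    w[names(weights)] <- unlist(weights)
  }
  w
}

accept_log <- function(delta) {
  is.finite(delta) && (delta >= 0 || log(stats::runif(1)) < delta) ||
    (is.infinite(delta) && delta > 0)
}

# draw the full history from its prior, conditioned on coalescence: returns
# NULL on a no-coalescence draw (to be counted as a rejected proposal)
propose_history <- function(cumA, leaves, tau) {
  n <- ncol(cumA)
  G <- base::matrix(0L, tau, n)
  for (j in seq_len(n))
    G[, j] <- findInterval(stats::runif(tau), cumA[j, ]) + 1L
  tri <- trace_lineages_int(G, leaves)
  if (is.null(tri$tree)) return(NULL)
  list(G = G, tree = tri$tree, occ = occ_matrix(tri, tau, n))
}

occ_matrix <- function(tri, tau, n) {
  occ <- base::matrix(FALSE, tau, n)
  for (g in seq_len(tri$depth)) occ[g, tri$occupied[[g]]] <- TRUE
  occ
}

gibbs_root_state <- function(lp, rp) {
  w <- rp * exp(lp - max(lp[is.finite(lp)], -745))
  if (!any(w > 0)) return(which.max(lp))
  sample.int(length(w), 1L, prob = w)
}

gibbs_x_state <- function(tree, Q, lstates, pos, S, k) {
  lps <- vector("list", k)
  wl <- numeric(k)
  for (s in seq_len(k)) {
    lstates[pos] <- s
    lps[[s]] <- root_log_partials(tree, Q, lstates)
    wl[s] <- lps[[s]][S]
  }
  w <- exp(wl - max(wl))
  s_new <- sample.int(k, 1L, prob = w)
  list(state = s_new, lp = lps[[s_new]])
}

init_x_states <- function(obs) {
  l <- length(obs$infer)
  if (l == 0) return(integer(0))
  oi <- as.integer(names(obs$observed))
  if (!is.null(obs$layout) && all(c("row", "col") %in% names(obs$layout))) {
    lay <- obs$layout
    vapply(obs$infer, function(p) {
      d2 <- (lay$row[oi] - lay$row[p])^2 + (lay$col[oi] - lay$col[p])^2
      unname(obs$observed[which.min(d2)])
    }, integer(1))
  } else {
    # no geometry: nearest by index
    vapply(obs$infer, function(p) {
      unname(obs$observed[which.min(abs(oi - p))])
    }, integer(1))
  }
}

# recording skeleton: retained-iteration mask and trace column names; the
# samplers fill a local matrix in place (a closure would copy it every write)
trace_skeleton <- function(config, param_names, obs) {
  keep <- seq(config$burnin + 1L, config$iterations, by = config$thin)
  keep_set <- logical(config$iterations)
  keep_set[keep] <- TRUE
  x_names <- if (length(obs$infer)) paste0("x_", obs$infer) else character(0)
  cols <- c("iteration", param_names, "s_root", x_names,
            "tmrca", "mrca_population", "log_likelihood", "log_root_prior",
            "log_history_prior", "log_prior", "log_posterior")
  list(keep_set = keep_set, nkeep = length(keep), cols = cols)
}

finish_mcmc <- function(mat, trees, tree_idx, att, acc, config, obs,
                        algorithm, pool, priors) {
  draws <- tibble::as_tibble(as.data.frame(mat))
  int_cols <- intersect(c("iteration", "s_root", "mrca_population", "tmrca",
                          grep("^x_", names(draws), value = TRUE)),
                        names(draws))
  draws[int_cols] <- lapply(draws[int_cols], as.integer)
  if (algorithm == "heuristic_pool") draws$tree_index <- tree_idx
  acceptance <- tibble::tibble(
    move = names(att), attempts = as.integer(att),
    accepts = as.integer(acc),
    rate = ifelse(att > 0, acc / att, NA_real_)
  )
  structure(list(draws = draws, trees = trees, acceptance = acceptance,
                 config = config, obs = obs, algorithm = algorithm,
                 pool = pool, priors = priors),
            class = "cultree_mcmc")
}

#' @export
print.cultree_mcmc <- function(x, ...) {
  cat("<cultree_mcmc>", x$algorithm, "sampler:",
      nrow(x$draws), "retained samples of", x$config$iterations,
      "iterations (burn-in", x$config$burnin, ", thin", x$config$thin, ")\n")
  print(x$acceptance)
  invisible(x)
}

#' Genealogies retained by a sampler run
#'
#' @param fit A `"cultree_mcmc"` object.
#' @return A list of [genealogy()] objects, one per stored sample (every
#'   `tree_thin`-th retained sample for the exact sampler; every retained
#'   sample for the heuristic sampler, looked up in its pool).
#' @export
sampled_trees <- function(fit) {
  stopifnot(inherits(fit, "cultree_mcmc"))
  if (fit$algorithm == "heuristic_pool")
    return(fit$pool$trees[fit$draws$tree_index])
  fit$trees[!vapply(fit$trees, is.null, logical(1))]
}
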