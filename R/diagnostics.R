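#' Effective sample size of an MCMC trace
#'
#' Geyer's initial-monotone-sequence estimator: autocovariances are summed
#' in adjacent pairs, truncated at the first non-positive pair and forced
#' monotone non-increasing, giving a consistent (and for reversible chains
#' conservative) estimate of the integrated autocorrelation time.
#'
#' @param x A numeric trace vector, or a `"cultree_mcmc"` fit.
#' @param parameter Column name of the draw to analyse when `x` is a fit.
#' @return The effective sample size (at most `length(x)`), or `NA` with a
#'   warning for a constant trace.
#' @examples
#' effective_sample_size(rnorm(1000))
#' @export
effective_sample_size <- function(x, parameter = NULL) {
  if (inherits(x, "cultree_mcmc")) {
    if (is.null(parameter)) stop("`parameter` is required for a fit object")
    if (!parameter %in% names(x$draws)) stop("unknown parameter: ", parameter)
    x <- as.numeric(x$draws[[parameter]])
  }
  x <- as.numeric(x)
  N <- length(x)
  if (N < 100) stop("need at least 100 samples for an ESS estimate")
  if (stats::var(x) == 0) {
    warning("constant trace: ESS undefined")
    return(NA_real_)
  }
  lag_max <- min(N - 1L, 2000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE,
                   type = "covariance")$acf[, 1, 1]
  g0 <- ac[1]
  # Gamma_k = gamma_{2k} + gamma_{2k+1}; truncate at the first non-positive
  # pair, then force the sequence monotone non-increasing
  npair <- length(ac) %/% 2L
  Gammas <- ac[2L * seq_len(npair) - 1L] + ac[2L * seq_len(npair)]
  nonpos <- which(Gammas <= 0)
  if (length(nonpos)) Gammas <- Gammas[seq_len(nonpos[1] - 1L)]
  if (length(Gammas) == 0) return(N)
  Gammas <- cummin(Gammas)
  sigma2 <- -g0 + 2 * sum(Gammas)
  if (sigma2 <= 0) return(N)
  min(N, N * g0 / sigma2)
}

#' Posterior state probabilities of inference-target populations
#'
#' Empirical frequency of each state among the retained draws, per target
#' population.
#'
#' @param fit A `"cultree_mcmc"` object.
#' @param populations Target population indices (default: all targets).
#' @return A tibble with columns `population`, `state`, `probability`
#'   (probabilities sum to 1 within each population).
#' @export
posterior_state_marginals <- function(fit, populations = NULL) {
  stopifnot(inherits(fit, "cultree_mcmc"))
  targets <- fit$obs$infer
  if (is.null(populations)) populations <- targets
  bad <- setdiff(populations, targets)
  if (length(bad))
    stop("not inference-target populations: ", toString(bad))
  k <- fit$obs$k
  out <- lapply(populations, function(p) {
    draws <- fit$draws[[paste0("x_", p)]]
    tibble::tibble(population = p, state = seq_len(k),
                   probability = tabulate(draws, nbins = k) / length(draws))
  })
  dplyr::bind_rows(out)
}

free_param_names <- function(fit) {
  pr <- c(fit$priors$theta_tau, fit$priors$theta_mu)
  names(pr)[!vapply(pr, `[[`, logical(1), "fixed")]
}

#' Tidy summary of sampled parameters
#'
#' One row per model parameter (sampled transmission and mutation
#' parameters plus the TMRCA), with posterior mean, standard deviation,
#' central 95% credible interval and effective sample size.
#'
#' @param x A `"cultree_mcmc"` object.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `ess`.
#' @export
tidy.cultree_mcmc <- function(x, conf_level = 0.95, ...) {
  terms <- c(free_param_names(x), "tmrca")
  a <- (1 - conf_level) / 2
  rows <- lapply(terms, function(nm) {
    v <- as.numeric(x$draws[[nm]])
    qs <- stats::quantile(v, c(a, 1 - a), names = FALSE, type = 1)
    ess <- if (length(v) >= 100 && stats::var(v) > 0)
      effective_sample_size(v) else NA_real_
    tibble::tibble(term = nm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = qs[1], conf.high = qs[2], ess = ess)
  })
  dplyr::bind_rows(rows)
}

#' One-line summary of a sampler run
#'
#' @param x A `"cultree_mcmc"` object.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, iterations, burn-in, retained
#'   draws, mean log posterior, and overall acceptance rate across
#'   Metropolis moves.
#' @export
glance.cultree_mcmc <- function(x, ...) {
  mh <- x$acceptance[!x$acceptance$move %in% c("s", "x"), ]
  tibble::tibble(
    algorithm = x$algorithm,
    iterations = x$config$iterations,
    burnin = x$config$burnin,
    retained = nrow(x$draws),
    mean_log_posterior = mean(x$draws$log_posterior),
    acceptance_rate = sum(mh$accepts) / max(1, sum(mh$attempts))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
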