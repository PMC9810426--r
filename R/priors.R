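#' Uniform and point-mass parameter priors
#'
#' All model parameters carry independent uniform priors `U(lo, hi)`.
#' A point mass (`prior_fixed()`) holds a parameter constant during
#' sampling while still entering every density — the documented default
#' for the grid rate `d` on large grids, where `d` mixes too slowly to be
#' estimated jointly.
#'
#' @param lo,hi Lower and upper bounds, `lo <= hi`.
#' @param value Fixed parameter value.
#' @return A `"param_prior"` list with fields `lo`, `hi`, `fixed`.
#' @export
prior_uniform <- function(lo, hi) {
  if (!(lo < hi)) stop("prior_uniform needs lo < hi")
  structure(list(lo = lo, hi = hi, fixed = FALSE), class = "param_prior")
}

#' @rdname prior_uniform
#' @export
prior_fixed <- function(value) {
  structure(list(lo = value, hi = value, fixed = TRUE), class = "param_prior")
}

#' Bundle parameter priors for inference
#'
#' @param theta_tau Named list of [prior_uniform()]/[prior_fixed()] priors
#'   for the transmission parameters (e.g. `list(d = prior_fixed(0.15))`).
#' @param theta_mu Named list of priors for the mutation parameters (e.g.
#'   `list(q12 = prior_uniform(0, 0.1), q21 = prior_uniform(0, 0.1))`).
#' @return A `"prior_config"` object.
#' @export
prior_config <- function(theta_tau = list(), theta_mu = list()) {
  chk <- function(l, what) {
    if (length(l) && (is.null(names(l)) || any(names(l) == "")))
      stop(what, " priors must be named")
    for (p in l) if (!inherits(p, "param_prior"))
      stop(what, " priors must be built with prior_uniform()/prior_fixed()")
    l
  }
  structure(list(theta_tau = chk(theta_tau, "theta_tau"),
                 theta_mu = chk(theta_mu, "theta_mu")),
            class = "prior_config")
}

prior_means <- function(priors) {
  vapply(priors, function(p) (p$lo + p$hi) / 2, numeric(1))
}

log_prior_density <- function(priors, values) {
  tot <- 0
  for (nm in names(priors)) {
    p <- priors[[nm]]
    v <- values[[nm]]
    if (v < p$lo || v > p$hi) return(-Inf)
    if (!p$fixed) tot <- tot - log(p$hi - p$lo)
  }
  tot
}

# reflecting uniform random-walk proposal inside [lo, hi]; symmetric
reflect_propose <- function(x, step, lo, hi) {
  y <- x + stats::runif(1, -step, step)
  width <- hi - lo
  # fold into [lo, lo + 2 width] then reflect
  y <- (y - lo) %% (2 * width)
  if (y > width) y <- 2 * width - y
  lo + y
}

#' MCMC run configuration
#'
#' @param iterations Total chain length (including burn-in).
#' @param burnin Iterations to discard (default 10% of `iterations`).
#' @param thin Keep every `thin`-th post-burn-in sample (default 10).
#' @param seed Integer RNG seed (required: runs must be reproducible).
#' @param weights Named non-negative move weights.  Exact-sampler moves:
#'   `g_entry`, `g_column`, `g_resim`, `theta_tau`, `theta_mu`, `s`, `x`;
#'   heuristic-sampler moves: `tree`, `theta_mu`, `s`, `x`.  Unspecified
#'   moves take the algorithm's defaults; inapplicable moves (no targets,
#'   all parameters fixed) are dropped automatically.
#' @param steps Named random-walk half-widths for the continuous
#'   parameters; default is 1/10 of each prior's range.
#' @param tree_thin Keep every `tree_thin`-th retained sample's genealogy
#'   (default 1: every retained sample).
#' @param init_retries Attempts at finding a coalescing initial history.
#' @return An `"mcmc_config"` object.
#' @export
mcmc_config <- function(iterations, burnin = NULL, thin = 10L, seed,
                        weights = NULL, steps = NULL, tree_thin = 1L,
                        init_retries = 1000L) {
  if (missing(seed)) stop("`seed` is required")
  iterations <- as.integer(iterations)
  if (is.null(burnin)) burnin <- as.integer(floor(iterations * 0.1))
  if (iterations <= burnin) stop("`iterations` must exceed `burnin`")
  if (!is.null(weights)) {
    if (any(unlist(weights) < 0) || all(unlist(weights) == 0))
      stop("move weights must be nonnegative and not all zero")
  }
  structure(list(iterations = iterations, burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 weights = weights, steps = steps,
                 tree_thin = as.integer(tree_thin),
                 init_retries = as.integer(init_retries)),
            class = "mcmc_config")
}
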