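#' Draw one genealogy from the tree prior by backward simulation
#'
#' Lineages are traced backward in time directly under the transmission
#' model, without materializing a history matrix: a lineage currently in
#' population `i` moves to population `j` with probability `A[i, j]` each
#' generation, and lineages occupying the same population coalesce.  The
#' simulation stops when a single lineage remains; if that takes more than
#' `tau_max` generations the draw is discarded as `NULL`
#' (no-coalescence).  Conditional on success this is an exact draw from
#' the genealogy prior restricted to `TMRCA <= tau_max` — the same law as
#' tracing a prior-distributed history matrix with `tau_max` rows.
#'
#' @param A A [transmission_matrix()].
#' @param leaves Distinct population indices of the traced copies.
#' @param tau_max Truncation horizon in generations.
#' @param cumA Optional precomputed row-wise cumulative probabilities of
#'   `A` (a speed-up for repeated calls).
#' @return A [genealogy()], or `NULL` if coalescence did not complete
#'   within `tau_max` generations.
#' @seealso [build_prior_pool()], [trace_lineages()]
#' @export
sample_prior_tree <- function(A, leaves, tau_max, cumA = NULL) {
  stopifnot(inherits(A, "transmission_matrix"))
  n <- nrow(A)
  leaves <- as.integer(leaves)
  if (anyDuplicated(leaves)) stop("`leaves` must be distinct")
  if (any(leaves < 1L) || any(leaves > n)) stop("leaf indices out of range 1..n")
  if (is.null(cumA)) cumA <- row_cumprobs(A)

  m <- length(leaves)
  node_of <- seq_len(m)
  pop_of <- leaves
  parent <- rep(NA_integer_, m)
  age <- rep(0L, m)
  population <- leaves
  if (m == 1L) return(new_genealogy(parent, age, population, leaves))

  nxt <- m
  for (g in seq_len(tau_max)) {
    nl <- length(pop_of)
    u <- stats::runif(nl)
    pop_of <- rowSums(u > cumA[pop_of, , drop = FALSE]) + 1L
    if (anyDuplicated(pop_of)) {
      for (p in unique(pop_of[duplicated(pop_of)])) {
        idx <- which(pop_of == p)
        nxt <- nxt + 1L
        parent <- c(parent, NA_integer_)
        age <- c(age, g)
        population <- c(population, p)
        parent[node_of[idx]] <- nxt
        node_of <- c(node_of[-idx], nxt)
        pop_of <- c(pop_of[-idx], p)
      }
      if (length(node_of) == 1L)
        return(new_genealogy(parent, age, population, leaves))
    }
  }
  NULL
}

#' Build a pool of prior genealogies
#'
#' Repeatedly draws transmission parameters from their prior, realizes the
#' transmission matrix, and simulates the backward coalescent until
#' `pool_size` successful trees are collected.  The pool — an empirical
#' sample from the joint prior of (transmission parameters, genealogy)
#' conditioned on coalescence within `tau_max` — is the ingredient of the
#' heuristic sampler, which replaces the intractable history-matrix prior
#' by this empirical measure.
#'
#' @param spec_fn Function mapping a named list of transmission-parameter
#'   draws to a [transmission_spec()] (e.g.
#'   `function(p) transmission_spec("grid", L = 4, d = p$d)`).
#' @param prior A [prior_config()] describing the transmission-parameter
#'   priors (only its `theta_tau` block is used).  Point-mass (fixed)
#'   parameters are allowed.
#' @param leaves Leaf population indices shared by every tree.
#' @param pool_size Number of successful trees to collect.
#' @param tau_max Truncation horizon in generations.
#' @param seed Integer seed.
#' @param max_reject_rate Abort if the running rejection fraction exceeds
#'   this ceiling after 1000 attempts (default 0.999): the horizon is too
#'   small or transmission too weak for lineages to meet.
#' @return An object of class `"prior_tree_pool"`: list with `trees`,
#'   `theta` (tibble of parameter draws, one row per tree), `leaves`,
#'   `tau_max`, `attempted`.
#' @examples
#' pr <- prior_config(theta_tau = list(d = prior_uniform(0.1, 0.2)))
#' pool <- build_prior_pool(function(p) transmission_spec("grid", L = 3, d = p$d),
#'                          pr, leaves = c(1, 5, 9), pool_size = 50,
#'                          tau_max = 500, seed = 1)
#' pool
#' @export
build_prior_pool <- function(spec_fn, prior, leaves, pool_size, tau_max,
                             seed = NULL, max_reject_rate = 0.999) {
  if (!is.null(seed)) set.seed(seed)
  theta_names <- names(prior$theta_tau)
  if (length(theta_names) == 0) stop("prior has no transmission parameters")
  trees <- vector("list", pool_size)
  theta <- base::matrix(NA_real_, pool_size, length(theta_names),
                        dimnames = list(NULL, theta_names))
  got <- 0L
  attempted <- 0L
  # cache A/cumA per theta draw only when theta is fixed (common case)
  all_fixed <- all(vapply(prior$theta_tau, function(p) p$lo == p$hi, logical(1)))
  cached <- NULL
  while (got < pool_size) {
    attempted <- attempted + 1L
    draw <- lapply(prior$theta_tau, function(p) stats::runif(1, p$lo, p$hi))
    if (all_fixed && !is.null(cached)) {
      A <- cached$A; cumA <- cached$cumA
    } else {
      A <- transmission_matrix(spec_fn(draw))
      cumA <- row_cumprobs(A)
      if (all_fixed) cached <- list(A = A, cumA = cumA)
    }
    tr <- sample_prior_tree(A, leaves, tau_max, cumA = cumA)
    if (!is.null(tr)) {
      got <- got + 1L
      trees[[got]] <- tr
      theta[got, ] <- unlist(draw)
    }
    if (attempted >= 1000L && (attempted - got) / attempted > max_reject_rate)
      stop(sprintf(
        "prior tree rejection rate %.4f exceeds ceiling %.4f: increase tau_max or strengthen transmission",
        (attempted - got) / attempted, max_reject_rate))
  }
  structure(list(trees = trees, theta = tibble::as_tibble(as.data.frame(theta)),
                 leaves = as.integer(leaves), tau_max = as.integer(tau_max),
                 attempted = attempted),
            class = "prior_tree_pool")
}

#' @export
print.prior_tree_pool <- function(x, ...) {
  cat("<prior_tree_pool>", length(x$trees), "trees on",
      length(x$leaves), "leaves; tau_max", x$tau_max,
      sprintf("; rejection rate %.3f\n",
              (x$attempted - length(x$trees)) / x$attempted))
  invisible(x)
}

#' Persist and reload a prior tree pool
#'
#' Trees are written as a NEXUS tree block (readable by standard tree
#' tools) and the parameter draws as a TSV alongside, so expensive pools
#' can be reused across inference runs.
#'
#' @param pool A `"prior_tree_pool"`.
#' @param tree_file Path of the NEXUS tree file.
#' @param theta_file Path of the parameter TSV (default: `tree_file` with
#'   extension `.tsv`).
#' @return `tree_file`, invisibly.
#' @export
write_prior_pool <- function(pool, tree_file,
                             theta_file = sub("\\.[^.]+$", ".tsv", tree_file)) {
  phys <- lapply(pool$trees, as_phylo)
  class(phys) <- "multiPhylo"
  ape::write.nexus(phys, file = tree_file)
  meta <- dplyr::mutate(pool$theta,
                        tmrca = vapply(pool$trees, tmrca, numeric(1)))
  utils::write.table(meta, theta_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tree_file)
}
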