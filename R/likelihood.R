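#' Felsenstein pruning on a single-trait genealogy
#'
#' Computes the probability of the leaf states given the genealogy, the
#' mutation matrix and the root (MRCA) state by the pruning recursion: the
#' partial likelihood of an internal node in state `j` is the product over
#' its children `c` (at branch length `t_c` generations) of
#' \eqn{\sum_{j'} (Q^{t_c})_{j j'} L_c(j')}.  Multifurcating nodes simply
#' take the product over all children.  Computation is carried out in log
#' space with per-node scaling, so long branches and small rates are safe;
#' integer branch lengths make every `Q^t` exact.
#'
#' @param tree A [genealogy()].
#' @param Q A [mutation_matrix()].
#' @param leaf_states Integer states (`1..k`) of the leaves, either in the
#'   order of `tree$leaves` or named by population index.
#' @param S Root state in `1..k`.
#' @return The likelihood `P(leaf states | Q, tree, S)`.
#' @seealso [root_marginal_likelihood()]
#' @examples
#' G <- example_history()
#' tr <- trace_lineages(G, c(1, 2, 4, 5))
#' Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.1, q21 = 0.2))
#' pruning_likelihood(tr, Q, c(1, 1, 2, 2), S = 1)
#' @export
pruning_likelihood <- function(tree, Q, leaf_states, S) {
  lp <- root_log_partials(tree, Q, leaf_states)
  stopifnot(S >= 1, S <= length(lp))
  exp(lp[S])
}

#' Likelihood marginalized over the root state
#'
#' \eqn{\sum_S P(\text{root} = S) P(\text{leaves} \mid Q, T, S)}; used for
#' marginal summaries and for the Gibbs update of the ancestral state.
#'
#' @inheritParams pruning_likelihood
#' @param root_prior Probability vector over the `k` states; defaults to
#'   the root prior implied by `Q`'s spec (stationary by default).
#' @return The marginal likelihood.
#' @export
root_marginal_likelihood <- function(tree, Q, leaf_states, root_prior = NULL) {
  if (is.null(root_prior)) root_prior <- root_state_prior(Q)
  if (abs(sum(root_prior) - 1) > 1e-9) stop("`root_prior` must sum to 1")
  lp <- root_log_partials(tree, Q, leaf_states)
  sum(root_prior * exp(lp))
}

# Log partial-likelihood vector at the root: lp[j] = log P(leaves | root = j).
# The workhorse of both samplers.  leaf_states may be named by population.
root_log_partials <- function(tree, Q, leaf_states) {
  stopifnot(inherits(tree, "genealogy"), inherits(Q, "mutation_matrix"))
  spec <- attr(Q, "spec")
  k <- spec$k
  m <- length(tree$leaves)
  ls <- resolve_leaf_states(tree, leaf_states, k)

  nn <- length(tree$parent)
  if (nn == 1L) {             # single-leaf tree: leaf is the root
    lp <- rep(-Inf, k); lp[ls[1]] <- 0
    return(lp)
  }
  if (spec$family == "two_state")
    return(root_log_partials2(tree, spec$q12, spec$q21, ls, m, nn))
  logL <- base::matrix(-Inf, nn, k)
  logL[cbind(seq_len(m), ls)] <- 0

  # node indices are already in post-order (children precede parents), so a
  # single pass finalizes each internal node before its message is sent up
  acc <- base::matrix(0, nn, k)           # accumulated log messages
  for (v in seq_len(nn)) {
    if (v > m) logL[v, ] <- acc[v, ]
    p <- tree$parent[v]
    if (is.na(p)) next
    M <- matrix_power(Q, tree$age[p] - tree$age[v])
    lc <- logL[v, ]
    mx <- max(lc)
    msg <- as.vector(M %*% exp(lc - mx))
    acc[p, ] <- acc[p, ] + log(msg) + mx
  }
  logL[nn, ]
}

# specialization of the pruning pass for the closed-form two-state model:
# scalar transition entries, no matrix allocation per edge
root_log_partials2 <- function(tree, q12, q21, ls, m, nn) {
  s <- q12 + q21
  lambda <- 1 - s
  pi1 <- if (s > 0) q21 / s else 1
  pi2 <- if (s > 0) q12 / s else 0
  l1 <- rep(-Inf, nn); l1[which(ls == 1L)] <- 0
  l2 <- rep(-Inf, nn); l2[which(ls == 2L)] <- 0
  a1 <- numeric(nn); a2 <- numeric(nn)
  par <- tree$parent; age <- tree$age
  for (v in seq_len(nn)) {
    if (v > m) { l1[v] <- a1[v]; l2[v] <- a2[v] }
    p <- par[v]
    if (is.na(p)) next
    x1 <- l1[v]; x2 <- l2[v]
    mx <- if (x1 >= x2) x1 else x2
    if (mx == -Inf) { a1[p] <- -Inf; a2[p] <- -Inf; next }
    lt <- lambda^(age[p] - age[v])
    m11 <- pi2 * lt + pi1; m12 <- pi2 - pi2 * lt
    m21 <- pi1 - pi1 * lt; m22 <- pi1 * lt + pi2
    e1 <- exp(x1 - mx); e2 <- exp(x2 - mx)
    a1[p] <- a1[p] + log(m11 * e1 + m12 * e2) + mx
    a2[p] <- a2[p] + log(m21 * e1 + m22 * e2) + mx
  }
  c(l1[nn], l2[nn])
}

resolve_leaf_states <- function(tree, leaf_states, k) {
  m <- length(tree$leaves)
  if (!is.null(names(leaf_states))) {
    idx <- match(tree$leaves, as.integer(names(leaf_states)))
    if (any(is.na(idx)))
      stop("every leaf population needs an assigned state")
    leaf_states <- leaf_states[idx]
  }
  if (length(leaf_states) != m)
    stop("`leaf_states` must assign a state to each of the ", m, " leaves")
  ls <- as.integer(leaf_states)
  if (any(is.na(ls)) || any(ls < 1L) || any(ls > k))
    stop("leaf states must lie in 1..k (k mismatch?)")
  ls
}
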