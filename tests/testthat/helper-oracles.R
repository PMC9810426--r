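# Independent oracles used across test files.  These deliberately avoid the
# package's own algorithms: naive repeated multiplication, exhaustive
# enumeration, direct counting.

# naive t-fold matrix product
naive_power <- function(M, t) {
  out <- diag(nrow(M))
  for (i in seq_len(t)) out <- out %*% M
  out
}

# likelihood by exhaustive summation over internal-node states
brute_likelihood <- function(tree, Q, leaf_states, S) {
  nn <- length(tree$parent)
  m <- length(tree$leaves)
  k <- attr(Q, "spec")$k
  if (nn == 1L) return(as.numeric(leaf_states[1] == S))
  internals <- setdiff(seq.int(m + 1L, nn), nn)
  combs <- if (length(internals))
    as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  else base::matrix(integer(0), 1, 0)
  tot <- 0
  for (r in seq_len(nrow(combs))) {
    st <- integer(nn)
    st[seq_len(m)] <- leaf_states
    st[nn] <- S
    if (length(internals)) st[internals] <- combs[r, ]
    p <- 1
    for (v in seq_len(nn - 1L)) {
      pa <- tree$parent[v]
      p <- p * matrix_power(Q, tree$age[pa] - tree$age[v])[st[pa], st[v]]
    }
    tot <- tot + p
  }
  tot
}

# exhaustive prior distribution of (TMRCA, MRCA population) for 2 traced
# copies on an n-population network with history depth tau, conditioned on
# coalescence; enumerates all n^(tau*n) histories weighted by Eq. of the
# transmission prior
enumerate_pair_coalescent <- function(A, leaves, tau) {
  n <- nrow(A)
  cells <- tau * n
  total <- n^cells
  col_of_cell <- rep(seq_len(n), each = tau)
  digits <- integer(cells)
  G <- base::matrix(1L, tau, n)
  logA <- log(A)
  res <- new.env(parent = emptyenv())
  for (h in seq_len(total)) {
    w <- exp(sum(logA[cbind(col_of_cell, as.vector(G))]))
    tr <- trace_lineages(history_matrix(G), leaves)
    if (!is.null(tr)) {
      key <- paste(tmrca(tr), mrca_population(tr))
      res[[key]] <- (if (is.null(res[[key]])) 0 else res[[key]]) + w
    }
    if (h < total) {
      i <- 1L
      repeat {
        digits[i] <- digits[i] + 1L
        if (digits[i] < n) break
        digits[i] <- 0L
        i <- i + 1L
      }
      G[] <- digits + 1L
    }
  }
  keys <- ls(res)
  p <- vapply(keys, function(k) res[[k]], numeric(1))
  stats::setNames(p / sum(p), keys)
}

# total-variation distance between two probability vectors aligned by name
tv_dist <- function(p, q) {
  keys <- union(names(p), names(q))
  p <- ifelse(is.na(p[keys]), 0, p[keys])
  q <- ifelse(is.na(q[keys]), 0, q[keys])
  0.5 * sum(abs(p - q))
}

# empirical TMRCA distribution (named) from a vector of draws
tmrca_probs <- function(x) {
  tb <- table(x)
  stats::setNames(as.numeric(tb) / length(x), names(tb))
}

tree_clade_keys <- function(tr) cultree:::tree_clades(tr)

# strip class/spec/cache attributes for plain-matrix comparisons
unclass_m <- function(M) {
  attr(M, "spec") <- NULL
  attr(M, "cache") <- NULL
  class(M) <- "matrix"
  M
}

random_stochastic <- function(k) {
  M <- base::matrix(stats::runif(k * k, 0.05, 1), k, k)
  M / rowSums(M)
}
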