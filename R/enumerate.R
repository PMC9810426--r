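#' Exact posterior by exhaustive enumeration (tiny instances)
#'
#' For networks small enough that every possible history matrix can be
#' listed (`n^(tau*n)` of them), the joint posterior of the latent
#' history, the ancestral state `S` and the unknown states `X` is computed
#' exactly: each history is weighted by its prior probability under `A`,
#' traced to a genealogy (histories whose lineages fail to coalesce
#' within `tau` generations carry zero likelihood), and combined with the
#' pruning likelihood for every `(S, X)` assignment.  Transmission and
#' mutation parameters are held fixed.  This provides the gold standard
#' against which the MCMC samplers are validated.
#'
#' @param obs An [observation_set()].
#' @param A A [transmission_matrix()].
#' @param Q A [mutation_matrix()].
#' @param tau History depth in generations.
#' @param max_histories Safety cap on `n^(tau*n)` (default `2^21`).
#' @return A list with tibbles `x_marginals` (`population`, `state`,
#'   `probability`), `s_marginal` (`state`, `probability`), `tmrca`
#'   (`tmrca`, `probability`), and the scalar `log_evidence`.
#' @export
enumerate_posterior <- function(obs, A, Q, tau, max_histories = 2^21) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(A, "transmission_matrix"),
            inherits(Q, "mutation_matrix"))
  n <- obs$n
  k <- obs$k
  cells <- tau * n
  total <- n^cells
  if (total > max_histories)
    stop(sprintf("n^(tau*n) = %g histories exceed the enumeration cap", total))

  leaves <- leaf_populations(obs)
  m <- length(obs$observed)
  l <- length(obs$infer)
  rp <- root_state_prior(Q)
  x_assign <- as.matrix(expand.grid(rep(list(seq_len(k)), max(l, 1))))
  if (l == 0) x_assign <- base::matrix(integer(0), 1, 0)
  n_x <- nrow(x_assign)

  # aggregate prior weight of histories per distinct traced genealogy
  tree_weight <- new.env(parent = emptyenv())
  tree_store <- new.env(parent = emptyenv())
  logA <- log(A)
  col_of_cell <- rep(seq_len(n), each = tau)   # cell order: column-major
  digits <- integer(cells)                      # current history, 0-based
  G <- base::matrix(1L, tau, n)
  p_nocoal <- 0

  for (h in seq_len(total)) {
    tri <- trace_lineages_int(G, leaves)
    lw <- sum(logA[cbind(col_of_cell, as.vector(G))])
    if (is.null(tri$tree)) {
      p_nocoal <- p_nocoal + exp(lw)
    } else {
      key <- paste(tri$tree$parent, tri$tree$age, tri$tree$population,
                   collapse = ";")
      w0 <- tree_weight[[key]]
      if (is.null(w0)) {
        tree_weight[[key]] <- exp(lw)
        tree_store[[key]] <- tri$tree
      } else tree_weight[[key]] <- w0 + exp(lw)
    }
    # increment base-n counter
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

  keys <- ls(tree_weight)
  s_mass <- numeric(k)
  tmrca_mass <- new.env(parent = emptyenv())
  evidence <- 0
  x_marg <- if (l > 0) base::matrix(0, l, k) else NULL

  for (key in keys) {
    tr <- tree_store[[key]]
    w <- tree_weight[[key]]
    tm <- as.character(tmrca(tr))
    for (xi in seq_len(n_x)) {
      ls_vec <- leaf_states(obs, as.integer(x_assign[xi, seq_len(l)]))
      lp <- root_log_partials(tr, Q, ls_vec)
      like <- rp * exp(lp)           # per root state S
      mass <- w * like               # joint weight per S
      tot <- sum(mass)
      if (tot == 0) next
      evidence <- evidence + tot
      s_mass <- s_mass + mass
      tmrca_mass[[tm]] <- (tmrca_mass[[tm]] %||% 0) + tot
      if (l > 0)
        for (t1 in seq_len(l))
          x_marg[t1, x_assign[xi, t1]] <- x_marg[t1, x_assign[xi, t1]] + tot
    }
  }
  if (evidence <= 0) stop("data have zero probability under the model (tau too small?)")

  tmk <- ls(tmrca_mass)
  tmrca_tbl <- tibble::tibble(
    tmrca = as.integer(tmk),
    probability = vapply(tmk, function(s) tmrca_mass[[s]], numeric(1)) / evidence
  )
  tmrca_tbl <- dplyr::arrange(tmrca_tbl, .data$tmrca)

  x_tbl <- if (l > 0) {
    dplyr::bind_rows(lapply(seq_len(l), function(t1) {
      tibble::tibble(population = obs$infer[t1], state = seq_len(k),
                     probability = x_marg[t1, ] / evidence)
    }))
  } else tibble::tibble(population = integer(0), state = integer(0),
                        probability = numeric(0))

  list(
    x_marginals = x_tbl,
    s_marginal = tibble::tibble(state = seq_len(k),
                                probability = s_mass / evidence),
    tmrca = tmrca_tbl,
    log_evidence = log(evidence),
    p_no_coalescence = p_nocoal
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
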