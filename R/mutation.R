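#' Specify a mutation model over discrete cultural states
#'
#' Mutation acts after transmission in every generation: a state `i` turns
#' into `j` with probability `q_ij`, collected in a row-stochastic `k` by
#' `k` matrix \eqn{Q}.  Families:
#'
#' * `"uniform"` — a single rate `mu` shared by every ordered state pair:
#'   \eqn{q_{ii} = 1 - \mu}, \eqn{q_{ij} = \mu/(k-1)} for \eqn{i \neq j}.
#'   The rate is spread over the \eqn{k - 1} alternative states so that the
#'   total per-generation mutation probability is `mu` regardless of `k`.
#' * `"two_state"` — `k = 2` with asymmetric rates `q12` (state 1 to 2) and
#'   `q21` (state 2 to 1).  Powers \eqn{Q^t} have a closed form in terms of
#'   \eqn{\lambda = 1 - q_{12} - q_{21}} and the stationary probabilities
#'   \eqn{\pi_1 = q_{21}/(q_{12}+q_{21})}, \eqn{\pi_2 = q_{12}/(q_{12}+q_{21})}.
#' * `"explicit"` — a user-supplied row-stochastic matrix (validated, never
#'   renormalized).
#'
#' @param family One of `"uniform"`, `"two_state"`, `"explicit"`.
#' @param k Number of states (2 for `"two_state"`).
#' @param mu Total per-generation mutation probability (uniform family).
#' @param q12,q21 Two-state rates, each in `[0, 1]`.
#' @param matrix Explicit `k` by `k` matrix.
#' @param root_prior Prior on the state of the most recent common ancestor:
#'   `"stationary"` (dominant left eigenvector of `Q`; the default),
#'   `"uniform"`, or a fixed probability vector of length `k`.
#' @return An object of class `"mutation_spec"`.
#' @seealso [mutation_matrix()], [matrix_power()], [stationary_distribution()]
#' @examples
#' mutation_spec("two_state", q12 = 0.04, q21 = 0.08)
#' mutation_spec("uniform", k = 3, mu = 0.06)
#' @export
mutation_spec <- function(family = c("uniform", "two_state", "explicit"),
                          k = NULL, mu = NULL, q12 = NULL, q21 = NULL,
                          matrix = NULL, root_prior = "stationary") {
  family <- match.arg(family)
  spec <- switch(family,
    uniform = {
      stopifnot(is.numeric(k), length(k) == 1L, k >= 2)
      if (is.null(mu) || mu < 0 || mu > 1)
        stop("uniform family needs a rate `mu` in [0, 1]")
      list(k = as.integer(k), mu = mu)
    },
    two_state = {
      if (is.null(q12) || is.null(q21) || q12 < 0 || q12 > 1 || q21 < 0 || q21 > 1)
        stop("two_state family needs rates `q12`, `q21` in [0, 1]")
      lambda <- 1 - q12 - q21
      if (abs(lambda) > 1) stop("two_state rates give |lambda| > 1")
      list(k = 2L, q12 = q12, q21 = q21)
    },
    explicit = {
      Q <- as.matrix(matrix)
      validate_stochastic(Q, "mutation matrix")
      list(k = nrow(Q), matrix = Q)
    }
  )
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("stationary", "uniform"))
  } else {
    root_prior <- as.numeric(root_prior)
    if (length(root_prior) != spec$k || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-9)
      stop("fixed `root_prior` must be a length-k probability vector")
  }
  structure(c(list(family = family, root_prior = root_prior), spec),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec> family:", x$family, " k:", x$k, "\n")
  invisible(x)
}

#' Realize the mutation matrix of a model specification
#'
#' @param spec A [mutation_spec()].
#' @return A `k` by `k` row-stochastic matrix of class `"mutation_matrix"`
#'   carrying the spec and a power cache as attributes.
#' @examples
#' mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
#' @export
mutation_matrix <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  Q <- switch(spec$family,
    uniform = {
      k <- spec$k
      M <- base::matrix(spec$mu / (k - 1), k, k)
      diag(M) <- 1 - spec$mu
      M
    },
    two_state = rbind(c(1 - spec$q12, spec$q12),
                      c(spec$q21, 1 - spec$q21)),
    explicit = spec$matrix
  )
  validate_stochastic(Q, "mutation matrix")
  structure(Q, class = c("mutation_matrix", "matrix"), spec = spec,
            cache = new.env(parent = emptyenv()))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix>", attr(x, "spec")$family, "model,",
      attr(x, "spec")$k, "states\n")
  y <- x
  attr(y, "spec") <- NULL
  attr(y, "cache") <- NULL
  class(y) <- "matrix"
  print(y)
  invisible(x)
}

#' Integer power of a mutation matrix
#'
#' Branch lengths of the single-trait genealogy are whole generations, so
#' only integer powers are ever needed.  For the two-state family the
#' analytic form
#' \deqn{Q^t = \begin{pmatrix} \pi_2\lambda^t + \pi_1 & -\pi_2\lambda^t + \pi_2 \\
#'   -\pi_1\lambda^t + \pi_1 & \pi_1\lambda^t + \pi_2 \end{pmatrix}}
#' is used; other families use exact repeated squaring.  Results are
#' memoized per `t` on the matrix object.
#'
#' @param Q A [mutation_matrix()].
#' @param t Non-negative integer number of generations.
#' @return A `k` by `k` transition matrix over `t` generations.
#' @examples
#' Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
#' matrix_power(Q, 7)
#' @export
matrix_power <- function(Q, t) {
  stopifnot(inherits(Q, "mutation_matrix"), t >= 0, t == round(t))
  k <- attr(Q, "spec")$k
  if (t == 0) return(diag(k))
  cache <- attr(Q, "cache")
  key <- as.character(t)
  if (!is.null(cache) && !is.null(got <- cache[[key]])) return(got)
  spec <- attr(Q, "spec")
  out <- if (spec$family == "two_state") {
    two_state_power(spec$q12, spec$q21, t)
  } else {
    mat_pow_squaring(unclass_mutation(Q), t)
  }
  if (!is.null(cache)) cache[[key]] <- out
  out
}

two_state_power <- function(q12, q21, t) {
  s <- q12 + q21
  if (s == 0) return(diag(2))
  lambda <- 1 - s
  pi1 <- q21 / s
  pi2 <- q12 / s
  lt <- lambda^t
  rbind(c(pi2 * lt + pi1, -pi2 * lt + pi2),
        c(-pi1 * lt + pi1, pi1 * lt + pi2))
}

mat_pow_squaring <- function(M, t) {
  k <- nrow(M)
  out <- diag(k)
  base <- M
  while (t > 0) {
    if (t %% 2 == 1) out <- out %*% base
    t <- t %/% 2
    if (t > 0) base <- base %*% base
  }
  out
}

unclass_mutation <- function(Q) {
  attr(Q, "spec") <- NULL
  attr(Q, "cache") <- NULL
  class(Q) <- "matrix"
  Q
}

#' Stationary distribution of the mutation process
#'
#' The long-run state frequencies \eqn{\pi} with \eqn{\pi Q = \pi}, used as
#' the default prior on the state of the most recent common ancestor.  The
#' chain must be irreducible and aperiodic (non-absorbing); otherwise the
#' stationary prior is undefined and a fixed or uniform root prior must be
#' supplied instead.
#'
#' @param Q A [mutation_matrix()].
#' @return A probability vector of length `k` with all entries positive.
#' @examples
#' Q <- mutation_matrix(mutation_spec("two_state", q12 = 0.04, q21 = 0.08))
#' stationary_distribution(Q)  # (2/3, 1/3)
#' @export
stationary_distribution <- function(Q) {
  stopifnot(inherits(Q, "mutation_matrix"))
  spec <- attr(Q, "spec")
  k <- spec$k
  if (spec$family == "two_state") {
    s <- spec$q12 + spec$q21
    if (s == 0)
      stop("mutation process is reducible (q12 = q21 = 0); stationary prior undefined")
    if (spec$q12 == 1 && spec$q21 == 1)
      stop("mutation process is periodic (q12 = q21 = 1); stationary prior undefined")
    return(c(spec$q21, spec$q12) / s)
  }
  M <- unclass_mutation(Q)
  # irreducible & aperiodic <=> some power has all entries > 0
  if (any(mat_pow_squaring(M, 4L * k) == 0))
    stop("mutation process is reducible or periodic; stationary prior undefined ",
         "(supply a fixed or uniform root prior)")
  e <- eigen(t(M))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v <= 0)) stop("failed to extract a positive stationary vector")
  v
}

#' Root-state prior implied by a mutation matrix
#'
#' @param Q A [mutation_matrix()].
#' @return Probability vector of length `k` according to the spec's
#'   `root_prior` mode.
#' @export
root_state_prior <- function(Q) {
  spec <- attr(Q, "spec")
  rp <- spec$root_prior
  if (is.numeric(rp)) return(rp)
  switch(rp,
    stationary = stationary_distribution(Q),
    uniform = rep(1 / spec$k, spec$k)
  )
}
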