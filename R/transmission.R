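#' Specify a transmission model for a population network
#'
#' A transmission model describes, for every ordered pair of populations
#' \eqn{(P_i, P_j)}, the per-generation probability \eqn{a_{ij}} that
#' \eqn{P_i} copies its cultural state from \eqn{P_j}.  The realized matrix
#' \eqn{A = (a_{ij})} is row stochastic and is obtained with
#' [transmission_matrix()].  Five families are supported:
#'
#' * `"island"` — complete graph with a single inter-population rate:
#'   \eqn{a_{ii} = 1 - c}, \eqn{a_{ij} = c/(n-1)} for \eqn{i \neq j}.
#' * `"per_population"` — as `"island"` but each population has its own
#'   outward-learning rate \eqn{c_i}: \eqn{a_{ii} = 1 - c_i},
#'   \eqn{a_{ij} = c_i/(n-1)}.
#' * `"gravity"` — populations preferentially learn from large and nearby
#'   populations: \eqn{a_{ij} \propto \pi_j \exp(-d_{ij}^2 / 2\sigma^2)}
#'   with \eqn{\pi_j} the size of \eqn{P_j} and \eqn{d_{ij}} the distance
#'   between \eqn{P_i} and \eqn{P_j}; rows are normalized.
#' * `"grid"` — an `L` by `L` square lattice (\eqn{n = L^2}): each square
#'   learns from each side-sharing neighbour with probability `d` and keeps
#'   its own state with probability \eqn{1 - d\,\mathrm{deg}(P_i)}.  Squares
#'   on edges and corners have degree 3 and 2 (no wraparound).
#' * `"explicit"` — a user-supplied row-stochastic matrix, validated but
#'   never silently renormalized.
#'
#' @param family One of `"island"`, `"per_population"`, `"gravity"`,
#'   `"grid"`, `"explicit"`.
#' @param n Number of populations (derived from `L` or the matrix where
#'   applicable).
#' @param c Inter-population learning rate in `[0, 1]` (island), or a
#'   length-`n` vector of such rates (per_population).
#' @param sigma Positive distance scale of the gravity kernel.
#' @param sizes Length-`n` vector of positive population sizes (gravity).
#' @param coords Data frame or matrix with columns `x`, `y` of node
#'   coordinates (gravity; Euclidean distances are computed), or `NULL` if
#'   `distances` is given.
#' @param distances Optional `n` by `n` symmetric matrix of pairwise
#'   distances (gravity).
#' @param L Side length of the square grid; `n = L^2`.
#' @param d Neighbour transmission rate of the grid model; must satisfy
#'   `1 - d * deg >= 0` for the maximal degree, i.e. `d <= 0.25` for an
#'   interior square.
#' @param matrix Explicit `n` by `n` row-stochastic matrix.
#'
#' @return An object of class `"transmission_spec"`.
#' @seealso [transmission_matrix()], [grid_layout()]
#' @examples
#' transmission_spec("island", n = 5, c = 0.2)
#' transmission_spec("grid", L = 4, d = 0.15)
#' @export
transmission_spec <- function(family = c("island", "per_population", "gravity",
                                         "grid", "explicit"),
                              n = NULL, c = NULL, sigma = NULL, sizes = NULL,
                              coords = NULL, distances = NULL, L = NULL,
                              d = NULL, matrix = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    island = {
      stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
      if (is.null(c) || length(c) != 1L || c < 0 || c > 1)
        stop("island family needs a single rate `c` in [0, 1]")
      list(n = as.integer(n), c = c)
    },
    per_population = {
      if (is.null(c) || any(c < 0) || any(c > 1))
        stop("per_population family needs rates `c` in [0, 1]")
      if (!is.null(n) && length(c) != n)
        stop("length of `c` must equal `n`")
      list(n = length(c), c = c)
    },
    gravity = {
      if (is.null(sigma) || sigma <= 0) stop("gravity family needs `sigma` > 0")
      if (is.null(sizes) || any(sizes <= 0))
        stop("gravity family needs positive population `sizes`")
      n <- length(sizes)
      if (is.null(distances)) {
        if (is.null(coords)) stop("gravity family needs `coords` or `distances`")
        coords <- as.matrix(coords[, c("x", "y")])
        if (nrow(coords) != n) stop("`coords` must have one row per population")
        distances <- as.matrix(stats::dist(coords))
      }
      if (!isTRUE(all.equal(dim(distances), c(n, n))))
        stop("`distances` must be n x n")
      list(n = n, sigma = sigma, sizes = sizes, distances = distances,
           coords = coords)
    },
    grid = {
      stopifnot(is.numeric(L), length(L) == 1L, L >= 1)
      if (is.null(d) || d < 0) stop("grid family needs a rate `d` >= 0")
      L <- as.integer(L)
      maxdeg <- if (L >= 3) 4L else if (L == 2) 2L else 0L
      if (maxdeg > 0 && 1 - d * maxdeg < 0)
        stop(sprintf(
          "grid family requires 1 - d * deg(P_i) >= 0 for all i (max degree %d, so d <= %.4g; got d = %g)",
          maxdeg, 1 / maxdeg, d))
      list(n = L^2L, L = L, d = d)
    },
    explicit = {
      A <- as.matrix(matrix)
      validate_stochastic(A, "transmission matrix")
      list(n = nrow(A), matrix = A)
    }
  )
  structure(c(list(family = family), spec), class = "transmission_spec")
}

#' @export
print.transmission_spec <- function(x, ...) {
  cat("<transmission_spec> family:", x$family, " n:", x$n, "\n")
  invisible(x)
}

validate_stochastic <- function(M, what, tol = 1e-12) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || !is.numeric(M))
    stop(what, " must be a square numeric matrix")
  if (any(M < 0) || any(M > 1))
    stop(what, " entries must lie in [0, 1]")
  dev <- max(abs(rowSums(M) - 1))
  if (dev > tol)
    stop(sprintf("%s rows must sum to 1 (max deviation %.3g)", what, dev))
  invisible(M)
}

#' Grid population layout
#'
#' Populations of an `L` by `L` grid are indexed row-major: population
#' `(r - 1) * L + c` sits at row `r`, column `c`.
#'
#' @param L Grid side length.
#' @return A tibble with columns `population`, `row`, `col`.
#' @export
grid_layout <- function(L) {
  L <- as.integer(L)
  tibble::tibble(
    population = seq_len(L^2),
    row = rep(seq_len(L), each = L),
    col = rep(seq_len(L), times = L)
  )
}

grid_neighbors <- function(L) {
  lay <- grid_layout(L)
  lapply(seq_len(L^2), function(i) {
    r <- lay$row[i]; cc <- lay$col[i]
    nb <- integer(0)
    if (r > 1) nb <- c(nb, i - L)
    if (r < L) nb <- c(nb, i + L)
    if (cc > 1) nb <- c(nb, i - 1L)
    if (cc < L) nb <- c(nb, i + 1L)
    nb
  })
}

#' Realize the transmission matrix of a model specification
#'
#' Deterministically maps a [transmission_spec()] to its row-stochastic
#' `n` by `n` matrix \eqn{A}, where `A[i, j]` is the probability that
#' population `i` copies the state of population `j` in one generation.
#'
#' @param spec A `"transmission_spec"`.
#' @return A numeric matrix of class `"transmission_matrix"` with the spec
#'   attached as attribute `"spec"`.
#' @examples
#' A <- transmission_matrix(transmission_spec("island", n = 3, c = 0.2))
#' rowSums(A)
#' @export
transmission_matrix <- function(spec) {
  stopifnot(inherits(spec, "transmission_spec"))
  n <- spec$n
  A <- switch(spec$family,
    island = {
      off <- if (n > 1) spec$c / (n - 1) else 0
      M <- base::matrix(off, n, n)
      diag(M) <- 1 - spec$c
      M
    },
    per_population = {
      M <- base::matrix(spec$c / max(n - 1, 1), n, n, byrow = FALSE)
      diag(M) <- 1 - spec$c
      M
    },
    gravity = {
      W <- exp(-spec$distances^2 / (2 * spec$sigma^2))
      W <- sweep(W, 2, spec$sizes, `*`)
      W / rowSums(W)
    },
    grid = {
      nb <- grid_neighbors(spec$L)
      M <- base::matrix(0, n, n)
      for (i in seq_len(n)) {
        M[i, nb[[i]]] <- spec$d
        M[i, i] <- 1 - spec$d * length(nb[[i]])
      }
      M
    },
    explicit = spec$matrix
  )
  dimnames(A) <- NULL
  validate_stochastic(A, "transmission matrix")
  structure(A, class = c("transmission_matrix", "matrix"), spec = spec)
}

#' @export
print.transmission_matrix <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("<transmission_matrix>", spec$family, "model,", spec$n, "populations\n")
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "spec") <- NULL
  class(x) <- "matrix"
  x
}

# Row-wise cumulative probabilities, cached on the matrix for fast
# categorical sampling of sources.
row_cumprobs <- function(A) {
  t(apply(A, 1, cumsum))
}
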