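#' Build an observation set from states and index lists
#'
#' An observation set records which populations have a known present-day
#' state (the data `Y`, size `m`), and which unobserved populations are
#' inference targets (the set `X`, size `l`).  Populations in neither list
#' are ignored entirely: they carry no data and their states are not
#' estimated.
#'
#' @param states Length-`n` integer vector of states in `1..k` (e.g. the
#'   output of [simulate_forward()]), read at `observed_idx`.
#' @param observed_idx Indices of the observed populations (at least one).
#' @param infer_idx Indices of the populations whose states are to be
#'   inferred; disjoint from `observed_idx`.
#' @param k Number of possible states; defaults to `max(states)`.
#' @param layout Optional tibble with columns `population`, `row`, `col`
#'   (or `x`, `y`) used for maps and I/O.
#' @return An object of class `"observation_set"`.
#' @seealso [read_dataset()], [simulate_forward()]
#' @export
mask_dataset <- function(states, observed_idx, infer_idx = integer(0),
                         k = max(states), layout = NULL) {
  n <- length(states)
  observed_idx <- as.integer(observed_idx)
  infer_idx <- as.integer(infer_idx)
  if (length(observed_idx) == 0) stop("at least one observed population is required")
  if (anyDuplicated(c(observed_idx, infer_idx)))
    stop("observed and inference-target indices must be pairwise distinct")
  if (any(c(observed_idx, infer_idx) < 1) || any(c(observed_idx, infer_idx) > n))
    stop("population indices out of range 1..n")
  if (any(states < 1) || any(states > k)) stop("states must lie in 1..k")
  observed <- as.integer(states[observed_idx])
  names(observed) <- observed_idx
  new_observation_set(n = n, k = as.integer(k), observed = observed,
                      infer = infer_idx, layout = layout,
                      truth = as.integer(states))
}

new_observation_set <- function(n, k, observed, infer, layout = NULL,
                                truth = NULL) {
  structure(list(n = n, k = k, observed = observed, infer = infer,
                 layout = layout, truth = truth),
            class = "observation_set")
}

#' Construct an observation set directly
#'
#' @param n Number of populations.
#' @param k Number of states.
#' @param observed Named integer vector: names are population indices,
#'   values their observed states in `1..k`.
#' @param infer Integer vector of inference-target population indices.
#' @param layout Optional layout tibble (see [mask_dataset()]).
#' @return An `"observation_set"`.
#' @export
observation_set <- function(n, k, observed, infer = integer(0), layout = NULL) {
  if (is.null(names(observed))) stop("`observed` must be named by population index")
  idx <- as.integer(names(observed))
  obs <- as.integer(observed)
  names(obs) <- idx
  infer <- as.integer(infer)
  if (length(obs) < 1) stop("at least one observed population is required (m >= 1)")
  if (anyDuplicated(c(idx, infer))) stop("observed and target indices overlap")
  if (any(c(idx, infer) < 1) || any(c(idx, infer) > n))
    stop("population indices out of range 1..n")
  if (any(obs < 1) || any(obs > k)) stop("observed states must lie in 1..k")
  new_observation_set(as.integer(n), as.integer(k), obs, infer, layout)
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> n:", x$n, " k:", x$k,
      " observed:", length(x$observed),
      " inference targets:", length(x$infer), "\n")
  invisible(x)
}

#' @rdname mask_dataset
#' @param x An `"observation_set"`.
#' @param ... Unused.
#' @export
as_tibble.observation_set <- function(x, ...) {
  status <- rep("unobserved", x$n)
  state <- rep(NA_integer_, x$n)
  status[x$infer] <- "infer"
  oi <- as.integer(names(x$observed))
  status[oi] <- "observed"
  state[oi] <- x$observed
  out <- tibble::tibble(population = seq_len(x$n), status = status,
                        state = state)
  if (!is.null(x$layout)) out <- dplyr::left_join(out, x$layout, by = "population")
  out
}

# leaf set used for genealogies: observed populations then inference targets
leaf_populations <- function(obs) {
  c(as.integer(names(obs$observed)), obs$infer)
}

# states for those leaves given a current draw of X
leaf_states <- function(obs, x_states = integer(0)) {
  stopifnot(length(x_states) == length(obs$infer))
  c(unname(obs$observed), as.integer(x_states))
}
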