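#' Clade frequencies across a genealogy sample
#'
#' A clade is the set of leaf populations below an internal node.  Every
#' tree in the sample must share the same leaf label set.  Leaf singletons
#' and the root clade are included (frequency 1 by construction).
#'
#' @param trees List of [genealogy()] objects (e.g. [sampled_trees()]).
#' @return A tibble with columns `clade` (leaf populations, sorted,
#'   comma-separated), `size`, and `frequency` in `[0, 1]`.
#' @export
clade_frequencies <- function(trees) {
  if (length(trees) == 0) stop("empty tree sample")
  leafset <- sort(trees[[1]]$leaves)
  counts <- new.env(parent = emptyenv())
  sizes <- new.env(parent = emptyenv())
  for (tr in trees) {
    if (!identical(sort(tr$leaves), leafset))
      stop("all trees must share the same leaf label set")
    for (key in tree_clades(tr)) {
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      if (is.null(sizes[[key]]))
        sizes[[key]] <- length(strsplit(key, ",", fixed = TRUE)[[1]])
    }
  }
  keys <- ls(counts)
  out <- tibble::tibble(
    clade = keys,
    size = vapply(keys, function(k) sizes[[k]], numeric(1), USE.NAMES = FALSE),
    frequency = vapply(keys, function(k) counts[[k]], numeric(1),
                       USE.NAMES = FALSE) / length(trees)
  )
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$clade)
}

# character keys of all clades (one per node) of a genealogy
tree_clades <- function(tr) {
  nn <- length(tr$parent)
  m <- length(tr$leaves)
  below <- vector("list", nn)
  for (v in seq_len(m)) below[[v]] <- tr$leaves[v]
  if (nn > m)
    for (v in seq_len(nn - 1L)) {
      p <- tr$parent[v]
      below[[p]] <- c(below[[p]], below[[v]])
    }
  vapply(below, function(x) paste(sort(x), collapse = ","), character(1))
}

#' Maximum clade credibility tree of a genealogy sample
#'
#' Selects the sampled tree maximizing the product of its clades'
#' frequencies in the sample (computed in log space), the summary used by
#' standard tree annotators.  Ties are broken by first occurrence in
#' sample order.  Each node of the winner is annotated with its clade's
#' support and the mean age of that clade's ancestral node across the
#' trees containing it.
#'
#' @param trees List of [genealogy()] objects sharing one leaf set.
#' @return The winning `"genealogy"` with extra fields `support` and
#'   `mean_age` (per node) and attribute `"log_clade_credibility"`.
#' @seealso [clade_frequencies()]
#' @export
mcc_tree <- function(trees) {
  if (length(trees) == 0) stop("empty tree sample")
  freq <- clade_frequencies(trees)
  ftab <- stats::setNames(freq$frequency, freq$clade)
  # mean node age per clade
  age_sum <- new.env(parent = emptyenv())
  age_n <- new.env(parent = emptyenv())
  for (tr in trees) {
    keys <- tree_clades(tr)
    for (v in seq_along(keys)) {
      key <- keys[v]
      age_sum[[key]] <- (age_sum[[key]] %||% 0) + tr$age[v]
      age_n[[key]] <- (age_n[[key]] %||% 0) + 1
    }
  }
  best <- -Inf; best_tree <- NULL; best_keys <- NULL
  for (tr in trees) {
    keys <- tree_clades(tr)
    sc <- sum(log(ftab[keys]))
    if (sc > best + 1e-12) { best <- sc; best_tree <- tr; best_keys <- keys }
  }
  best_tree$support <- unname(ftab[best_keys])
  best_tree$mean_age <- vapply(best_keys, function(k) age_sum[[k]] / age_n[[k]],
                               numeric(1), USE.NAMES = FALSE)
  attr(best_tree, "log_clade_credibility") <- best
  best_tree
}

#' State concordance of sampled clades
#'
#' For each sampled genealogy, the fraction of its internal clades
#' (excluding the root and leaf singletons) whose leaves all carry the
#' same observed state; averaged over the sample.  Comparing this
#' statistic between prior and posterior tree samples quantifies how far
#' the data pull clades towards grouping same-state populations.
#'
#' @param trees List of [genealogy()] objects.
#' @param states Named integer vector: states of the leaf populations
#'   (names are population indices).
#' @return Mean concordance in `[0, 1]` (trees with no non-root internal
#'   clade contribute the tree-wide concordance of the root clade).
#' @export
clade_state_concordance <- function(trees, states) {
  stopifnot(length(trees) > 0, !is.null(names(states)))
  st <- stats::setNames(as.integer(states), names(states))
  val <- vapply(trees, function(tr) {
    nn <- length(tr$parent)
    m <- length(tr$leaves)
    keys <- tree_clades(tr)
    idx <- setdiff(seq.int(m + 1L, nn), nn)
    if (length(idx) == 0) idx <- nn         # star tree: use the root clade
    mono <- vapply(idx, function(v) {
      pops <- strsplit(keys[v], ",", fixed = TRUE)[[1]]
      s <- st[pops]
      as.numeric(length(unique(s)) == 1L)
    }, numeric(1))
    mean(mono)
  }, numeric(1))
  mean(val)
}

#' Spatial map of posterior state probabilities
#'
#' Combines observed states and posterior marginals of the inference
#' targets into one table per population, suitable for plotting or
#' writing as TSV.
#'
#' @param obs An [observation_set()] with a grid layout (or one supplied
#'   via `layout`).
#' @param marginals Tibble from [posterior_state_marginals()] (or the
#'   enumeration oracle's `x_marginals`).
#' @param layout Optional layout tibble overriding `obs$layout`.
#' @return A tibble with columns `population`, `row`, `col`, `status`
#'   (`observed` / `infer` / `unobserved`), `state` (observed state or
#'   `NA`) and `p_state_1` ... `p_state_k` (degenerate for observed
#'   populations).
#' @export
state_map <- function(obs, marginals = NULL, layout = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  lay <- layout %||% obs$layout
  if (is.null(lay)) stop("a grid layout is required for a state map")
  if (nrow(lay) != obs$n) stop("layout size does not match the network")
  k <- obs$k
  base <- as_tibble_obs_layout(obs, lay)
  probs <- base::matrix(NA_real_, obs$n, k)
  oi <- as.integer(names(obs$observed))
  probs[oi, ] <- 0
  probs[cbind(oi, obs$observed)] <- 1
  if (!is.null(marginals) && nrow(marginals)) {
    for (r in seq_len(nrow(marginals)))
      probs[marginals$population[r], marginals$state[r]] <-
        marginals$probability[r]
  }
  colnames(probs) <- paste0("p_state_", seq_len(k))
  dplyr::bind_cols(base, tibble::as_tibble(probs))
}

as_tibble_obs_layout <- function(obs, lay) {
  tb <- as_tibble.observation_set(obs)
  tb$row <- NULL; tb$col <- NULL
  dplyr::left_join(tb, lay[, c("population", "row", "col")], by = "population")
}
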