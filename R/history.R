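#' Transmission-history matrices
#'
#' A history matrix `G` encodes the last `tau` generations of copying
#' events on an `n`-population network: `G[i, j]` is the population from
#' which `P_j` copied its state `i - 1` generations ago, so row 1 is the
#' copying event that produced the present generation.  `tau` is the
#' assumed upper bound on the age of the most recent common ancestor of
#' the traced state copies.
#'
#' @param mat Integer `tau` by `n` matrix with entries in `1..n`.
#' @return An integer matrix of class `"history_matrix"`.
#' @seealso [trace_lineages()], [transition_counts()], [example_history()]
#' @export
history_matrix <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  n <- ncol(mat)
  if (any(is.na(mat)) || any(mat < 1L) || any(mat > n))
    stop("history matrix entries must be population indices in 1..n")
  structure(mat, class = c("history_matrix", "matrix"))
}

#' @export
print.history_matrix <- function(x, ...) {
  cat("<history_matrix> tau:", nrow(x), " n:", ncol(x), "\n")
  print(base::matrix(as.integer(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Worked-example history matrix
#'
#' A small 6-generation history of five populations used throughout the
#' documentation and tests.  Tracing any four of the five present-day
#' copies through it gives a most recent common ancestor in population 3,
#' five generations ago.
#'
#' @return A 6 by 5 `"history_matrix"`.
#' @examples
#' G <- example_history()
#' tmrca(trace_lineages(G, c(1, 2, 4, 5)))
#' @export
example_history <- function() {
  history_matrix(rbind(
    c(1L, 2L, 3L, 4L, 4L),
    c(2L, 3L, 2L, 4L, 5L),
    c(1L, 3L, 3L, 5L, 5L),
    c(1L, 2L, 3L, 4L, 4L),
    c(1L, 3L, 3L, 3L, 5L),
    c(2L, 1L, 3L, 4L, 5L)
  ))
}

#' Count copying events per ordered population pair
#'
#' `c[i, j]` is the number of generations, among the `tau` recorded in
#' `G`, in which population `i` copied from population `j`; each row sums
#' to `tau`.
#'
#' @param G A [history_matrix()].
#' @return An `n` by `n` integer matrix.
#' @export
transition_counts <- function(G) {
  stopifnot(inherits(G, "history_matrix"))
  n <- ncol(G)
  cnt <- base::matrix(0L, n, n)
  for (i in seq_len(n)) cnt[i, ] <- tabulate(G[, i], nbins = n)
  cnt
}

#' Log prior probability of a history matrix
#'
#' Under the transmission model every entry of `G` is an independent draw
#' from the corresponding row of `A`, so
#' \eqn{\log P(G \mid \theta_\tau) = \sum_{ij} c_{ij} \log a_{ij}}.
#' Histories using a forbidden transition (`a_ij = 0`) have probability
#' zero, returned as `-Inf`.
#'
#' @param counts Output of [transition_counts()] (or a history matrix,
#'   which is counted first).
#' @param A A [transmission_matrix()].
#' @return The log prior probability (possibly `-Inf`).
#' @export
log_history_prior <- function(counts, A) {
  if (inherits(counts, "history_matrix")) counts <- transition_counts(counts)
  stopifnot(nrow(counts) == nrow(A))
  used <- counts > 0L
  if (any(A[used] == 0)) return(-Inf)
  sum(counts[used] * log(A[used]))
}

# ---- genealogy -------------------------------------------------------------

#' Single-trait genealogies
#'
#' A genealogy is the rooted (possibly multifurcating) tree of one
#' cultural trait's copies.  Leaves are present-day populations at age 0;
#' internal nodes are coalescences: generations (ages) at which two or
#' more traced lineages occupied the same population.  Branch lengths are
#' whole generations.  Internally the tree is a compact parent-array:
#' nodes `1..m` are leaves in the order of `leaves`, the root is the last
#' node.
#'
#' @param parent Integer vector: `parent[v]` is the parent node of `v`
#'   (`NA` for the root).
#' @param age Integer node ages in generations before present.
#' @param population Population index of each node.
#' @param leaves Population indices of the leaf nodes `1..m`.
#' @return An object of class `"genealogy"`.
#' @seealso [trace_lineages()], [tmrca()], [as_phylo()]
#' @export
genealogy <- function(parent, age, population, leaves) {
  validate_genealogy(new_genealogy(parent, age, population, leaves))
}

# unvalidated constructor for hot paths whose output is correct by design
new_genealogy <- function(parent, age, population, leaves) {
  structure(list(parent = as.integer(parent), age = as.integer(age),
                 population = as.integer(population),
                 leaves = as.integer(leaves)),
            class = "genealogy")
}

validate_genealogy <- function(g) {
  m <- length(g$leaves)
  nn <- length(g$parent)
  if (sum(is.na(g$parent)) != 1L || !is.na(g$parent[nn]))
    stop("genealogy must have exactly one root, stored last")
  if (m > 1 && any(g$age[seq_len(m)] != 0L)) stop("leaf ages must be 0")
  ok <- !is.na(g$parent)
  if (any(g$age[g$parent[ok]] <= g$age[ok]))
    stop("ages must strictly increase towards the root")
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", length(x$leaves), "leaves, TMRCA", tmrca(x),
      "generations, MRCA in population", x$population[length(x$parent)], "\n")
  invisible(x)
}

#' Time to the most recent common ancestor
#'
#' @param tree A `"genealogy"`.
#' @return Root age in generations (0 for a single-leaf tree).
#' @export
tmrca <- function(tree) {
  stopifnot(inherits(tree, "genealogy"))
  tree$age[length(tree$age)]
}

#' Population holding the most recent common ancestor
#'
#' @param tree A `"genealogy"`.
#' @return Population index of the root node.
#' @export
mrca_population <- function(tree) {
  stopifnot(inherits(tree, "genealogy"))
  tree$population[length(tree$population)]
}

#' Trace lineages through a history matrix
#'
#' Starting from one lineage per requested present-day population, each
#' lineage sitting in population `p` at depth `g - 1` generations moves to
#' population `G[g, p]` at depth `g`; lineages that land in the same
#' population have, by construction, a single common ancestral copy and
#' merge into one node (multifurcating if three or more arrive at once).
#' Tracing stops when one lineage remains.  If more than one lineage
#' survives all `tau` recorded generations the history contradicts the
#' prior bound on the MRCA age and `NULL` is returned (the zero-likelihood
#' case).
#'
#' @param G A [history_matrix()].
#' @param leaves Distinct population indices of the present-day copies to
#'   trace.
#' @return A `"genealogy"`, or `NULL` if the lineages do not coalesce
#'   within `tau` generations.
#' @examples
#' trace_lineages(example_history(), c(1, 2, 4, 5))
#' @export
trace_lineages <- function(G, leaves) {
  stopifnot(inherits(G, "history_matrix"))
  leaves <- as.integer(leaves)
  if (length(leaves) == 0) stop("`leaves` must be non-empty")
  if (anyDuplicated(leaves)) stop("`leaves` must be distinct")
  if (any(leaves < 1L) || any(leaves > ncol(G)))
    stop("leaf indices out of range 1..n")
  trace_lineages_int(G, leaves)$tree
}

# Core tracer. Also returns the occupancy list used by the exact sampler:
# occupied[[g]] = populations holding >= 1 lineage at depth g - 1 (i.e. the
# populations whose row-g entries are read).  Works on any integer matrix.
trace_lineages_int <- function(G, leaves) {
  tau <- nrow(G)
  m <- length(leaves)
  # per-lineage state: node id and current population
  node_of <- seq_len(m)
  pop_of <- leaves
  parent <- rep(NA_integer_, m)
  age <- rep(0L, m)
  population <- leaves
  occupied <- vector("list", tau)

  if (m == 1L) {
    tree <- new_genealogy(parent, age, population, leaves)
    return(list(tree = tree, occupied = occupied, depth = 0L))
  }

  nxt <- m
  for (g in seq_len(tau)) {
    occupied[[g]] <- unique(pop_of)
    pop_of <- G[g, pop_of]
    # group lineages now sharing a population
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
      if (length(node_of) == 1L) {
        tree <- new_genealogy(parent, age, population, leaves)
        return(list(tree = tree, occupied = occupied, depth = g))
      }
    }
  }
  list(tree = NULL, occupied = occupied, depth = tau)
}

# children list (by node) for pruning; root last in post-order guaranteed by
# construction (children always created before their parent? not guaranteed
# for leaves, but ages are: a simple age order works).
children_list <- function(tree) {
  nn <- length(tree$parent)
  ch <- vector("list", nn)
  for (v in seq_len(nn - 1L)) {
    p <- tree$parent[v]
    ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# ---- interop with ape ------------------------------------------------------

#' Convert a genealogy to an ape "phylo" tree
#'
#' Leaf labels are `P<population>`; internal nodes carry their population
#' index as node labels, and edge lengths are branch lengths in
#' generations.  Multifurcations are preserved.
#'
#' @param tree A `"genealogy"`.
#' @param tip_labels Optional character vector of leaf labels (in the
#'   order of `tree$leaves`).
#' @return An object of class `"phylo"`.
#' @export
as_phylo <- function(tree, tip_labels = NULL) {
  stopifnot(inherits(tree, "genealogy"))
  m <- length(tree$leaves)
  nn <- length(tree$parent)
  if (is.null(tip_labels)) tip_labels <- paste0("P", tree$leaves)
  if (m == 1L) {
    # single-leaf degenerate tree: represent as a 1-tip, 1-node phylo
    phy <- list(edge = base::matrix(c(2L, 1L), 1, 2), tip.label = tip_labels,
                edge.length = 0, Nnode = 1L,
                node.label = as.character(tree$population[1]))
    class(phy) <- "phylo"
    return(phy)
  }
  # ape numbering: tips 1..m, root m+1, then other internals
  internals <- (m + 1L):nn
  # root is node nn; assign ape ids
  ape_id <- integer(nn)
  ape_id[seq_len(m)] <- seq_len(m)
  ape_id[nn] <- m + 1L
  others <- setdiff(internals, nn)
  if (length(others)) ape_id[others] <- m + 1L + seq_along(others)
  kids <- which(!is.na(tree$parent))
  edge <- cbind(ape_id[tree$parent[kids]], ape_id[kids])
  elen <- tree$age[tree$parent[kids]] - tree$age[kids]
  phy <- list(edge = edge, tip.label = tip_labels,
              edge.length = as.numeric(elen),
              Nnode = nn - m,
              node.label = as.character(tree$population[c(nn, others)]))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a genealogy to a Newick file
#'
#' Branch lengths are in generations; internal node labels carry the
#' population index of each ancestral copy.
#'
#' @param tree A `"genealogy"`.
#' @param file Path to write to (or `""` to return the string).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_genealogy <- function(tree, file = "") {
  phy <- as_phylo(tree)
  ape::write.tree(phy, file = file)
}
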