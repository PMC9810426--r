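#' Read and write dataset files
#'
#' Datasets are TSV files with columns `population_id`, `row`, `col` (or
#' `x`, `y`), and `state`.  The state column holds an integer state in
#' `1..k`, `"?"` for an unobserved population that is ignored, or `"!"`
#' for an unobserved population whose state is to be inferred.  Indices
#' are 1-based throughout.
#'
#' @param path File path.
#' @param k Number of states; defaults to the largest state in the file.
#' @return [read_dataset()] returns an [observation_set()] (with the
#'   layout attached); [write_dataset()] returns `path` invisibly.
#' @export
read_dataset <- function(path, k = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"population_id" %in% names(df)) stop("missing column `population_id`")
  if (!"state" %in% names(df)) stop("missing column `state`")
  pid <- as.integer(df$population_id)
  if (anyDuplicated(pid)) stop("duplicate population ids in dataset")
  n <- length(pid)
  if (!setequal(pid, seq_len(n))) stop("population ids must be 1..n")
  ord <- order(pid)
  df <- df[ord, ]
  st_raw <- trimws(df$state)
  is_q <- st_raw == "?"
  is_x <- st_raw == "!"
  st <- suppressWarnings(as.integer(st_raw))
  if (any(is.na(st) & !is_q & !is_x))
    stop("state column must be an integer, '?' or '!'")
  if (all(is_q | is_x)) stop("dataset has no observed population")
  if (is.null(k)) k <- max(st, na.rm = TRUE)
  if (any(!is.na(st) & (st < 1 | st > k)))
    stop("observed states outside 1..k")
  layout <- NULL
  if (all(c("row", "col") %in% names(df))) {
    layout <- tibble::tibble(population = seq_len(n),
                             row = as.integer(df$row),
                             col = as.integer(df$col))
  } else if (all(c("x", "y") %in% names(df))) {
    layout <- tibble::tibble(population = seq_len(n),
                             row = as.numeric(df$y), col = as.numeric(df$x))
  }
  obs_idx <- which(!is_q & !is_x)
  observed <- stats::setNames(st[obs_idx], obs_idx)
  observation_set(n = n, k = k, observed = observed,
                  infer = which(is_x), layout = layout)
}

#' @rdname read_dataset
#' @param obs An [observation_set()].
#' @param truth Optional length-`n` vector of true states written for
#'   benchmarking as an extra `true_state` column.
#' @export
write_dataset <- function(obs, path, truth = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  st <- rep("?", obs$n)
  st[obs$infer] <- "!"
  oi <- as.integer(names(obs$observed))
  st[oi] <- as.character(obs$observed)
  lay <- obs$layout
  df <- data.frame(population_id = seq_len(obs$n),
                   row = if (!is.null(lay)) lay$row else NA,
                   col = if (!is.null(lay)) lay$col else NA,
                   state = st)
  if (!is.null(truth)) df$true_state <- as.integer(truth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write history matrices as CSV
#'
#' Plain integer CSV, `tau` rows by `n` columns, no header.
#'
#' @param G A [history_matrix()].
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_history <- function(G, path) {
  stopifnot(inherits(G, "history_matrix"))
  utils::write.table(unclass(G), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  history_matrix(m)
}

#' Write a genealogy sample as a NEXUS tree log
#'
#' Standard NEXUS `trees` block with a translate table, consumable by
#' common tree-annotation and visualization tools.
#'
#' @param trees List of [genealogy()] objects sharing one leaf set.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tree_log <- function(trees, path) {
  phys <- lapply(trees, as_phylo)
  class(phys) <- "multiPhylo"
  ape::write.nexus(phys, file = path, translate = TRUE)
  invisible(path)
}

#' Write a sampler trace as TSV
#'
#' One row per retained sample with parameters, ancestral and inferred
#' states, TMRCA and log-posterior components.
#'
#' @param fit A `"cultree_mcmc"` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "cultree_mcmc"))
  utils::write.table(fit$draws, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run metadata as JSON
#'
#' Configuration echo (seed, chain settings, acceptance rates) for
#' reproducibility records.
#'
#' @param fit A `"cultree_mcmc"` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(fit, path) {
  meta <- list(
    algorithm = fit$algorithm,
    package_version = as.character(utils::packageVersion("cultree")),
    config = unclass(fit$config),
    acceptance = fit$acceptance
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
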