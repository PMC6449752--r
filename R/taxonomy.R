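# Taxonomy trees.
#
# A taxonomy is a rooted forest of named clades (one root per top rank,
# e.g. the domains). Sequences are attached at the clade of their full
# taxonomic path; the sequences "belonging to" a clade are those attached
# at the clade itself plus all of its descendants. Clades are stored in a
# flat table and referenced by integer id; the string form of a clade's
# full path indexes it uniquely.

#' Build a taxonomy tree from sequence assignments
#'
#' Creates one clade per distinct path prefix occurring in the input and
#' attaches every sequence at the clade of its full path. Children keep
#' their insertion order.
#'
#' @param assignments Data frame with columns `seq_id` and `taxopath`
#'   (`";"`-separated path strings), as returned by [read_taxonomy()].
#' @return An object of class `taxonomy`: a list with parallel per-clade
#'   vectors `name`, `parent` (0 for top-rank clades), `path` (full path
#'   string) and lists `children` and `seq_ids`, plus `path_index` mapping
#'   path strings to clade ids.
#' @export
build_taxonomy <- function(assignments) {
  if (nrow(assignments) == 0L) value_error("empty assignment list")
  dup <- assignments$seq_id[duplicated(assignments$seq_id)]
  if (length(dup) > 0L) {
    format_error(sprintf("sequence '%s' assigned more than once", dup[[1]]))
  }
  name <- character()
  parent <- integer()
  path <- character()
  children <- list()
  seq_ids <- list()
  index <- new.env(parent = emptyenv())

  get_clade <- function(ranks) {
    key <- taxopath_string(ranks)
    id <- index[[key]]
    if (!is.null(id)) return(id)
    pid <- if (length(ranks) > 1L) get_clade(ranks[-length(ranks)]) else 0L
    id <- length(name) + 1L
    name[[id]] <<- ranks[[length(ranks)]]
    parent[[id]] <<- pid
    path[[id]] <<- key
    children[[id]] <<- integer()
    seq_ids[[id]] <<- character()
    if (pid > 0L) children[[pid]] <<- c(children[[pid]], id)
    index[[key]] <- id
    id
  }

  for (i in seq_len(nrow(assignments))) {
    ranks <- as_taxopath(assignments$taxopath[[i]])
    id <- get_clade(ranks)
    seq_ids[[id]] <- c(seq_ids[[id]], assignments$seq_id[[i]])
  }

  keys <- ls(index)
  structure(
    list(
      name = name, parent = parent, path = path,
      children = children, seq_ids = seq_ids,
      path_index = setNames(
        vapply(keys, function(k) index[[k]], integer(1)), keys
      )
    ),
    class = "taxonomy"
  )
}

#' Look up a clade id by taxopath
#'
#' @param tax A `taxonomy`.
#' @param path Taxopath (rank vector or `";"`-separated string).
#' @return Integer clade id.
#' @export
clade_id <- function(tax, path) {
  key <- taxopath_string(as_taxopath(path))
  id <- tax$path_index[[key]]
  if (is.null(id)) validation_error(sprintf("no clade with path '%s'", key))
  id
}

#' Top-rank clades of a taxonomy
#'
#' @param tax A `taxonomy`.
#' @return Integer ids of the root clades, in insertion order.
#' @export
taxonomy_roots <- function(tax) which(tax$parent == 0L)

# All clade ids in the subtree rooted at `id` (including `id`).
subtree_clades <- function(tax, id) {
  out <- integer()
  frontier <- id
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- unlist(tax$children[frontier], use.names = FALSE)
  }
  out
}

#' Sequences belonging to a clade
#'
#' The union of the sequence ids attached at the clade and at all of its
#' descendants.
#'
#' @param tax A `taxonomy`.
#' @param clade Integer clade id (see [clade_id()]) or a taxopath.
#' @param alignment Optional alignment matrix (see [read_alignment()]); if
#'   given, the corresponding rows are returned instead of the ids.
#' @return Character vector of sequence ids, or an alignment sub-matrix.
#'   Empty when the clade's subtree holds no sequences.
#' @export
clade_sequences <- function(tax, clade, alignment = NULL) {
  id <- if (is.numeric(clade)) as.integer(clade) else clade_id(tax, clade)
  if (id < 1L || id > length(tax$name)) validation_error("clade id out of range")
  ids <- unlist(tax$seq_ids[subtree_clades(tax, id)], use.names = FALSE)
  if (is.null(alignment)) return(ids)
  missing <- setdiff(ids, rownames(alignment))
  if (length(missing) > 0L) {
    validation_error(sprintf("sequence '%s' not in alignment", missing[[1]]))
  }
  alignment[ids, , drop = FALSE]
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf(
    "<taxonomy: %d clades (%d top-rank), %d attached sequences>\n",
    length(x$name), sum(x$parent == 0L),
    sum(lengths(x$seq_ids))
  ))
  invisible(x)
}
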