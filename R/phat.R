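# Automatic reference tree construction ("PhAT").
#
# Greedy taxonomy expansion: starting from the top-rank clades, repeatedly
# replace the candidate clade with the highest total sequence entropy by
# its immediate sub-clades, until the candidate list reaches the requested
# target size (or no candidate can be expanded). Each surviving candidate
# is then condensed into one consensus sequence; the set of consensus
# sequences is the input for maximum-likelihood inference of the reference
# tree (the inference itself is external to this package).

#' Expand a taxonomy into a target number of candidate clades
#'
#' Greedy loop: while the candidate count is below `target_count`, the
#' candidate with the highest clade entropy is removed and its immediate
#' sub-clades are added, updating the count by `-1 + #sub-clades`. Entropy
#' ties are broken lexicographically by full taxopath, making runs
#' deterministic. Leaf clades (no sub-clades) are never expanded: when the
#' entropy argmax is a leaf it is retained as a candidate and the next
#' expandable candidate is taken instead; the loop also terminates when
#' every candidate is a leaf, in which case the target is not met. Because
#' expanded clades can have many children, the final count may exceed the
#' target; the relative deviation is reported.
#'
#' @param tax A `taxonomy` (see [build_taxonomy()]).
#' @param alignment Alignment matrix holding the attached sequences.
#' @param target_count Desired number of candidate clades.
#' @param initial Optional integer clade ids (or list of taxopaths) to
#'   start from; defaults to the top-rank clades.
#' @return An object of class `candidate_set`: list with `candidates`
#'   (integer clade ids), `paths` (their full taxopath strings),
#'   `taxa_count`, `target_count`, `expansion_log` (paths in expansion
#'   order) and `deviation_pct` (`100 * |final - target| / target`).
#' @export
expand_taxonomy <- function(tax, alignment, target_count, initial = NULL) {
  if (is.null(initial)) {
    cand <- taxonomy_roots(tax)
  } else if (is.numeric(initial)) {
    cand <- as.integer(initial)
  } else {
    cand <- vapply(initial, function(p) clade_id(tax, p), integer(1))
  }
  if (length(cand) < 1L) value_error("need at least one initial candidate")
  if (!is_count(target_count) || target_count < length(cand)) {
    value_error("target_count must be a count >= the number of initial candidates")
  }

  cache <- new.env(parent = emptyenv())
  h_of <- function(id) clade_entropy(tax, id, alignment, cache = cache)
  taxa_count <- length(cand)
  log_paths <- character()

  while (taxa_count < target_count) {
    expandable <- cand[lengths(tax$children[cand]) > 0L]
    if (length(expandable) == 0L) break
    h <- vapply(expandable, h_of, numeric(1))
    best_h <- max(h)
    tied <- expandable[h == best_h]
    most_diverse <- tied[order(tax$path[tied])][[1]]
    kids <- tax$children[[most_diverse]]
    cand <- c(cand[cand != most_diverse], kids)
    taxa_count <- taxa_count - 1L + length(kids)
    log_paths <- c(log_paths, tax$path[[most_diverse]])
  }

  structure(
    list(
      candidates = cand,
      paths = tax$path[cand],
      taxa_count = taxa_count,
      target_count = as.integer(target_count),
      expansion_log = log_paths,
      deviation_pct = 100 * abs(taxa_count - target_count) / target_count
    ),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "<candidate_set: %d candidates (target %d, deviation %.2f%%), %d expansions>\n",
    x$taxa_count, x$target_count, x$deviation_pct, length(x$expansion_log)
  ))
  invisible(x)
}

#' Build consensus reference sequences for a candidate set
#'
#' For each candidate clade, all sequences in the clade and its sub-clades
#' are condensed into one consensus sequence (see [consensus()]). The tip
#' label of each record is its sanitized full taxopath (see
#' [sanitize_label()]). Candidates whose subtree holds no sequences are
#' dropped with a warning. As a baseline alternative, `method = "first"`
#' picks the clade's first attached sequence verbatim instead of building
#' a consensus.
#'
#' @param cands A `candidate_set` (see [expand_taxonomy()]).
#' @param tax The `taxonomy` the candidates refer to.
#' @param alignment Alignment matrix holding the attached sequences.
#' @param method Consensus method (`"majority"`, `"cavener"`,
#'   `"threshold"`) or `"first"`.
#' @param threshold Passed to [consensus()] for the `threshold` method.
#' @return A data frame with columns `taxopath`, `label`, `sequence`,
#'   `n_sequences`, one row per retained candidate.
#' @export
build_reference_set <- function(cands, tax, alignment,
                                method = "majority", threshold = 0.5) {
  rows <- lapply(cands$candidates, function(id) {
    ids <- clade_sequences(tax, id)
    if (length(ids) == 0L) {
      warning(sprintf("candidate '%s' has no sequences; dropped", tax$path[[id]]))
      return(NULL)
    }
    seqs <- alignment[ids, , drop = FALSE]
    seq <- if (identical(method, "first")) {
      paste(seqs[1L, ], collapse = "")
    } else {
      consensus(seqs, method = method, threshold = threshold)
    }
    data.frame(
      taxopath = tax$path[[id]],
      label = sanitize_label(tax$path[[id]]),
      sequence = seq,
      n_sequences = length(ids),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) value_error("all candidates have empty sequence sets")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a taxonomic constraint tree over candidate clades
#'
#' Emits a multifurcating newick tree (no branch lengths) whose tips are
#' the candidate labels and whose internal structure mirrors the taxonomy
#' restricted to the candidates' paths, collapsing ranks that do not split
#' the candidates. Suitable as a topological constraint for
#' maximum-likelihood inference, so that the inferred reference tree keeps
#' the taxonomy's high-level clades monophyletic.
#'
#' @param cands A `candidate_set`.
#' @param tax The `taxonomy` the candidates refer to.
#' @return A newick string.
#' @export
build_constraint_tree <- function(cands, tax) {
  if (length(cands$candidates) < 2L) {
    value_error("need at least 2 candidates for a constraint tree")
  }
  # canonical (lexicographic) candidate order for deterministic output
  ord <- order(tax$path[cands$candidates])
  paths <- lapply(tax$path[cands$candidates][ord], as_taxopath)
  labels <- vapply(tax$path[cands$candidates][ord], sanitize_label, character(1))

  render <- function(idx, depth) {
    # Candidates whose path ends at this depth are tips here; the rest
    # partition by their rank at depth + 1. No candidate is an ancestor
    # of another, so a terminal path never coexists with deeper ones
    # under the same prefix.
    terminal <- vapply(paths[idx], function(p) length(p) == depth, logical(1))
    if (all(terminal)) {
      if (length(idx) == 1L) return(labels[[idx]])
      return(paste0("(", paste(labels[idx], collapse = ","), ")"))
    }
    ranks <- vapply(paths[idx], function(p) p[[depth + 1L]], character(1))
    groups <- split(idx, factor(ranks, levels = unique(ranks)))
    parts <- vapply(
      groups,
      function(g) render(g, depth + 1L),
      character(1)
    )
    if (length(parts) == 1L) return(parts[[1]])
    paste0("(", paste(parts, collapse = ","), ")")
  }

  paste0(render(seq_along(paths), 0L), ";")
}
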