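# Multilevel ("Russian Doll") placement support.
#
# Instead of placing queries on one huge reference tree, queries are first
# placed on a broad backbone tree (BT) and then routed to smaller, refined
# clade trees (CTs) for a second placement level. Each CT is associated
# with a set of BT edges (possibly several, "overlapping" the BT); queries
# whose placement falls on an edge with no associated CT ("inner" edges)
# are filtered out — a phylogenetically informed alternative to
# similarity-based filtering.

#' Construct a clade association
#'
#' Maps every edge number of a backbone tree to a clade-tree label, or to
#' the reserved label `"inner"` for edges belonging to no clade tree.
#'
#' @param tree The backbone `edge_tree`.
#' @param edge_num Integer vector of edge numbers with a label.
#' @param label Character vector of labels, parallel to `edge_num`.
#' @return An object of class `clade_assoc`: list with `mapping` (named
#'   character vector over all tree edges; names are edge numbers) and
#'   `labels` (the distinct non-inner labels).
#' @export
clade_association <- function(tree, edge_num, label) {
  if (length(edge_num) != length(label)) {
    value_error("edge_num and label must have the same length")
  }
  nums <- edge_numbers(tree)
  unknown <- setdiff(edge_num, nums)
  if (length(unknown) > 0L) {
    validation_error(sprintf("association references unknown edge %d", unknown[[1]]))
  }
  if (anyDuplicated(edge_num)) {
    validation_error("an edge may carry only one label")
  }
  mapping <- setNames(rep(INNER_LABEL, length(nums)), as.character(nums))
  mapping[as.character(edge_num)] <- label
  structure(
    list(mapping = mapping, labels = sort(unique(label[label != INNER_LABEL]))),
    class = "clade_assoc"
  )
}

#' Read a clade association from a TSV file
#'
#' Two tab-separated columns: edge number, label. Edges absent from the
#' file default to `"inner"`.
#'
#' @param path Path to the TSV file.
#' @param tree The backbone `edge_tree`.
#' @return A `clade_assoc`.
#' @export
read_clade_association <- function(path, tree) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("edge_num", "label"),
                   colClasses = c("integer", "character"))
  clade_association(tree, df$edge_num, df$label)
}

#' Derive a clade association from taxopath prefixes
#'
#' Gives every *terminal* backbone edge whose tip label matches a clade's
#' taxopath prefix that clade's label; all other edges are `"inner"`. Tip
#' labels are assumed to be sanitized taxopaths as produced by
#' [build_reference_set()], so prefixes are matched after sanitization.
#'
#' @param tree The backbone `edge_tree` with taxopath tip labels.
#' @param paths Named character vector: clade-tree label -> taxopath
#'   prefix (`";"`-separated string).
#' @return A `clade_assoc`.
#' @export
clade_association_from_paths <- function(tree, paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    value_error("paths must be named by clade-tree label")
  }
  phy <- tree$phylo
  tip_rows <- which(phy$edge[, 2L] <= length(phy$tip.label))
  tip_labels <- phy$tip.label[phy$edge[tip_rows, 2L]]
  edge_num <- integer()
  label <- character()
  for (lab in names(paths)) {
    prefix <- sanitize_label(paths[[lab]])
    hit <- startsWith(tip_labels, prefix)
    edge_num <- c(edge_num, tree$edge_num[tip_rows[hit]])
    label <- c(label, rep(lab, sum(hit)))
  }
  if (anyDuplicated(edge_num)) {
    validation_error("clade path prefixes overlap: an edge matched two labels")
  }
  clade_association(tree, edge_num, label)
}

#' Route placed queries to clade trees
#'
#' Distributes the pqueries of a backbone placement document to the clade
#' trees their placements fall into.
#'
#' * `best_hit` (default): a pquery follows its single placement with the
#'   highest likelihood weight ratio. If that edge is `"inner"`, the
#'   pquery is filtered out. Routed and filtered pqueries partition the
#'   input.
#' * `mass_threshold`: a pquery is routed to *every* clade tree whose
#'   associated edges accumulate at least `threshold` of its LWR mass (so
#'   it can reach several clade trees); pqueries reaching no clade tree
#'   are filtered.
#'
#' @param doc A `placement_doc` placed on the backbone tree.
#' @param assoc A `clade_assoc` for that tree.
#' @param mode `"best_hit"` or `"mass_threshold"`.
#' @param threshold LWR mass threshold for `mass_threshold` mode.
#' @return An object of class `routing_result`: list with `routed` (named
#'   list label -> data frame `name`, `multiplicity`), `filtered` (same
#'   shape), `mode` and `threshold`.
#' @export
route <- function(doc, assoc, mode = c("best_hit", "mass_threshold"),
                  threshold = 0.5) {
  mode <- match.arg(mode)
  missing <- setdiff(edge_numbers(doc$tree), names(assoc$mapping))
  if (length(missing) > 0L) {
    validation_error(sprintf("edge %s missing from clade association", missing[[1]]))
  }
  empty <- data.frame(name = character(), multiplicity = numeric(),
                      stringsAsFactors = FALSE)
  routed <- setNames(
    rep(list(empty), length(assoc$labels)), assoc$labels
  )
  filtered <- empty

  for (pq in doc$pqueries) {
    pl <- pq$placements
    target <- if (mode == "best_hit") {
      lab <- assoc$mapping[[as.character(pl$edge_num[[which.max(pl$like_weight_ratio)]])]]
      if (lab == INNER_LABEL) character() else lab
    } else {
      mass <- tapply(
        pl$like_weight_ratio,
        assoc$mapping[as.character(pl$edge_num)],
        sum
      )
      mass <- mass[names(mass) != INNER_LABEL]
      names(mass)[mass >= threshold]
    }
    if (length(target) == 0L) {
      filtered <- rbind(filtered, pq$names)
    } else {
      for (lab in target) routed[[lab]] <- rbind(routed[[lab]], pq$names)
    }
  }
  structure(
    list(routed = routed, filtered = filtered, mode = mode,
         threshold = if (mode == "mass_threshold") threshold else NA_real_),
    class = "routing_result"
  )
}

#' Check that a clade's backbone edges are monophyletic
#'
#' A label's edge set is monophyletic when one split separates it from the
#' rest of the tree: either the set equals some edge plus all edges below
#' it (a single terminal edge is the smallest case), or it equals exactly
#' the edges strictly below some edge (which is then the separating
#' split). Monophyletic clade associations keep the two placement levels
#' consistent and are recommended when constructing the backbone (see
#' [build_constraint_tree()]).
#'
#' @param tree The backbone `edge_tree`.
#' @param assoc A `clade_assoc` for that tree.
#' @param label A clade-tree label present in `assoc`.
#' @return List with `monophyletic` (logical) and `edge` (the separating
#'   edge number if monophyletic, otherwise `NA`).
#' @export
check_monophyly <- function(tree, assoc, label) {
  edges <- as.integer(names(assoc$mapping)[assoc$mapping == label])
  if (length(edges) == 0L) {
    value_error(sprintf("label '%s' owns no edges", label))
  }
  for (e in edge_numbers(tree)) {
    sub <- subtree_edge_numbers(tree, e)
    if (setequal(sub, edges) || setequal(setdiff(sub, e), edges)) {
      return(list(monophyletic = TRUE, edge = e))
    }
  }
  list(monophyletic = FALSE, edge = NA_integer_)
}

#' Analytic cost model for multilevel placement
#'
#' Placement cost per query is linear in the number of reference taxa.
#' Placing each query once on a backbone of `n_bt` taxa and once on one
#' clade tree of `n_ct` taxa, instead of on a comprehensive tree of
#' `n_full` taxa, changes the computational cost by
#' `speedup = n_full / (n_bt + n_ct)`; peak memory is governed by the
#' largest tree held at a time, `memory_factor = n_full / max(n_bt,
#' n_ct)`. Splitting 10000 taxa into a 1000-taxon backbone and ten
#' 1000-taxon clade trees, for instance, cuts cost by 5x and memory 10x.
#'
#' @param n_full Taxa in the comprehensive tree.
#' @param n_bt Taxa in the backbone tree.
#' @param n_ct Taxa in (one of) the clade trees.
#' @return List with `speedup` and `memory_factor`.
#' @export
cost_model <- function(n_full, n_bt, n_ct) {
  for (x in list(n_full, n_bt, n_ct)) {
    if (!is_count(x)) value_error("taxa counts must be integers >= 1")
  }
  list(
    speedup = n_full / (n_bt + n_ct),
    memory_factor = n_full / max(n_bt, n_ct)
  )
}

#' @export
print.routing_result <- function(x, ...) {
  cat(sprintf(
    "<routing_result (%s): %s; filtered %d>\n",
    x$mode,
    paste(sprintf("%s: %d", names(x$routed),
                  vapply(x$routed, nrow, integer(1))), collapse = ", "),
    nrow(x$filtered)
  ))
  invisible(x)
}
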