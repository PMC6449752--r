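# Placement accuracy evaluation.
#
# A query built from a known database sequence is expected to land on the
# terminal edge of the consensus sequence that represents it (the
# candidate clade whose taxopath is the longest prefix of the query's
# taxopath). Accuracy is measured as the distance between actual and
# expected placement, in two flavors: the discrete number of branches
# between the two edges, and the continuous branch-length distance between
# the placement's attachment point and the nearest point of the expected
# edge (so any position on the expected edge scores 0). Since a pquery
# usually has several candidate placements, both distances are reported as
# LWR-weighted averages. Pendant lengths are off-tree and excluded
# throughout.

#' Expected placement edge of a query
#'
#' @param query_taxopath Taxopath of the query (rank vector or string).
#' @param ref_set Reference set data frame (see [build_reference_set()])
#'   with columns `taxopath` and `label`.
#' @param tree The reference `edge_tree` whose tips carry the labels.
#' @return The edge number of the terminal edge leading to the candidate
#'   with the longest taxopath prefix of the query, or `NA` if no
#'   candidate's path is a prefix (the query is unmapped).
#' @export
expected_edge <- function(query_taxopath, ref_set, tree) {
  q <- as_taxopath(query_taxopath)
  cand_paths <- lapply(ref_set$taxopath, as_taxopath)
  is_prefix <- vapply(cand_paths, function(p) taxopath_has_prefix(q, p), logical(1))
  if (!any(is_prefix)) return(NA_integer_)
  depths <- lengths(cand_paths)
  depths[!is_prefix] <- -1L
  best <- which.max(depths)
  terminal_edge_number(tree, ref_set$label[[best]])
}

# All-node distance matrix, cached on the tree via an attribute-free local
# environment: recomputed per call site instead (trees here are small).
node_dists <- function(tree) ape::dist.nodes(tree$phylo)

# Branch-length distance from the attachment point on edge `num` (at
# `distal` from the child-side node) to node `v`.
point_node_distance <- function(tree, D, num, distal, v) {
  info <- edge_info(tree, num)
  if (is.na(info$parent)) {
    # Root edge: paths leave it only through the root node.
    return(distal + D[info$child, v])
  }
  min(distal + D[info$child, v], (info$length - distal) + D[info$parent, v])
}

# Branch-length distance between two attachment points.
point_point_distance <- function(tree, D, e1, d1, e2, d2) {
  if (e1 == e2) return(abs(d1 - d2))
  info2 <- edge_info(tree, e2)
  if (is.na(info2$parent)) {
    return(d2 + point_node_distance(tree, D, e1, d1, info2$child))
  }
  min(
    d2 + point_node_distance(tree, D, e1, d1, info2$child),
    (info2$length - d2) + point_node_distance(tree, D, e1, d1, info2$parent)
  )
}

# Branch-length distance from an attachment point to the *nearest* point
# of edge e2 (0 if the point sits on e2).
point_edge_distance <- function(tree, D, e1, d1, e2) {
  if (e1 == e2) return(0)
  info2 <- edge_info(tree, e2)
  ends <- info2$child
  if (!is.na(info2$parent)) ends <- c(ends, info2$parent)
  min(vapply(ends, function(v) point_node_distance(tree, D, e1, d1, v), numeric(1)))
}

# Topological distances (number of branches) from edge `from` to every
# edge, by breadth-first search on the edge adjacency graph: two edges are
# adjacent (distance 1) iff they share a node; an edge's distance to
# itself is 0.
edge_topo_distances <- function(tree, from) {
  nums <- edge_numbers(tree)
  ends <- lapply(nums, function(e) {
    info <- edge_info(tree, e)
    c(info$child, if (!is.na(info$parent)) info$parent)
  })
  names(ends) <- as.character(nums)
  dist <- setNames(rep(NA_integer_, length(nums)), as.character(nums))
  if (!as.character(from) %in% names(dist)) {
    validation_error(sprintf("unknown edge number %s", from))
  }
  dist[[as.character(from)]] <- 0L
  frontier <- as.character(from)
  while (length(frontier) > 0L) {
    nodes <- unique(unlist(ends[frontier], use.names = FALSE))
    nxt <- names(ends)[vapply(ends, function(v) any(v %in% nodes), logical(1))]
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0L) break
    dist[nxt] <- dist[[frontier[[1]]]] + 1L
    frontier <- nxt
  }
  dist
}

#' Topological and branch-length distance between two edges
#'
#' The topological distance counts branches: 0 for the same edge, 1 for
#' edges sharing a node, else shortest-path length in the edge adjacency
#' graph. The branch-length distance is measured from an attachment point
#' on `e1` to the nearest point of `e2`; by default the attachment point
#' is the point of `e1` nearest to `e2`, giving a symmetric edge-to-edge
#' distance.
#'
#' @param tree An `edge_tree`.
#' @param e1,e2 Edge numbers.
#' @param distal Optional attachment position on `e1`, measured from its
#'   child-side node.
#' @return Named numeric vector `c(topo = ..., bl = ...)`.
#' @export
edge_distances <- function(tree, e1, e2, distal = NULL) {
  edge_info(tree, e2)  # errors on unknown edges
  topo <- edge_topo_distances(tree, e1)[[as.character(e2)]]
  D <- node_dists(tree)
  bl <- if (is.null(distal)) {
    if (e1 == e2) {
      0
    } else {
      info1 <- edge_info(tree, e1)
      ends1 <- list(c(0, info1$child))
      if (!is.na(info1$parent)) ends1 <- c(ends1, list(c(info1$length, info1$parent)))
      min(vapply(
        ends1,
        function(end) point_edge_distance(tree, D, e1, end[[1]], e2),
        numeric(1)
      ))
    }
  } else {
    point_edge_distance(tree, D, e1, distal, e2)
  }
  c(topo = as.numeric(topo), bl = bl)
}

#' LWR-weighted distances of a pquery to its expected edge
#'
#' Weighted averages `sum(lwr_i * d_i) / sum(lwr_i)` over the pquery's
#' placements, for both the topological and the branch-length distance.
#' Branch-length distances use each placement's `distal_length` as the
#' attachment point and nearest-point semantics on the expected edge.
#'
#' @param pq A pquery (list with `names`, `placements`).
#' @param expected Expected edge number.
#' @param tree The `edge_tree` the placements refer to.
#' @return Named numeric vector `c(topo = ..., bl = ...)`.
#' @export
weighted_distance <- function(pq, expected, tree) {
  pl <- pq$placements
  w <- pl$like_weight_ratio
  if (sum(w) <= 0) value_error("all placement weights are zero")
  topo_all <- edge_topo_distances(tree, expected)
  D <- node_dists(tree)
  d_topo <- topo_all[as.character(pl$edge_num)]
  distal <- if ("distal_length" %in% names(pl)) pl$distal_length else rep(0, nrow(pl))
  d_bl <- vapply(seq_len(nrow(pl)), function(i) {
    point_edge_distance(tree, D, pl$edge_num[[i]], distal[[i]], expected)
  }, numeric(1))
  c(topo = sum(w * d_topo) / sum(w), bl = sum(w * d_bl) / sum(w))
}

#' Expected distance between placement locations (EDPL)
#'
#' The LWR-weighted mean pairwise branch-length distance between a
#' pquery's attachment points: `sum_i sum_j p_i p_j d(i, j)` with the LWRs
#' `p` normalized to their sum. EDPL is 0 iff all placement mass sits at
#' one attachment point; low values indicate that the candidate placements
#' cluster in a small neighborhood of the tree.
#'
#' @param pq A pquery.
#' @param tree The `edge_tree` the placements refer to.
#' @return EDPL in branch-length units.
#' @export
edpl <- function(pq, tree) {
  pl <- pq$placements
  w <- pl$like_weight_ratio
  if (sum(w) <= 0) value_error("all placement weights are zero")
  p <- w / sum(w)
  if (nrow(pl) == 1L) return(0)
  D <- node_dists(tree)
  distal <- if ("distal_length" %in% names(pl)) pl$distal_length else rep(0, nrow(pl))
  total <- 0
  for (i in seq_len(nrow(pl) - 1L)) {
    for (j in seq(i + 1L, nrow(pl))) {
      d <- point_point_distance(
        tree, D,
        pl$edge_num[[i]], distal[[i]],
        pl$edge_num[[j]], distal[[j]]
      )
      total <- total + 2 * p[[i]] * p[[j]] * d
    }
  }
  total
}

#' Clade identification accuracy
#'
#' Fraction of queries whose most likely (best-hit) placement falls on a
#' backbone edge carrying their true clade label. Any edge with the right
#' label counts: overlapping associations make several edges correct.
#' Queries are weighted by their multiplicities.
#'
#' @param doc A `placement_doc` on the backbone tree.
#' @param assoc A `clade_assoc` for that tree.
#' @param truth Named character vector: query name -> true clade label.
#'   Must cover every pquery name.
#' @return List with `overall` (weighted fraction correct) and `per_label`
#'   (data frame `label`, `n`, `correct`, `accuracy`).
#' @export
clade_accuracy <- function(doc, assoc, truth) {
  rows <- lapply(doc$pqueries, function(pq) {
    pl <- pq$placements
    best_label <- assoc$mapping[[as.character(
      pl$edge_num[[which.max(pl$like_weight_ratio)]]
    )]]
    miss <- setdiff(pq$names$name, names(truth))
    if (length(miss) > 0L) {
      value_error(sprintf("no truth entry for query '%s'", miss[[1]]))
    }
    data.frame(
      name = pq$names$name,
      multiplicity = pq$names$multiplicity,
      truth = unname(truth[pq$names$name]),
      predicted = best_label,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df$correct <- df$truth == df$predicted
  per_label <- do.call(rbind, lapply(split(df, df$truth), function(g) {
    data.frame(
      label = g$truth[[1]],
      n = sum(g$multiplicity),
      correct = sum(g$multiplicity[g$correct]),
      stringsAsFactors = FALSE
    )
  }))
  per_label$accuracy <- per_label$correct / per_label$n
  rownames(per_label) <- NULL
  list(
    overall = sum(df$multiplicity[df$correct]) / sum(df$multiplicity),
    per_label = per_label
  )
}

#' Taxopaths of every edge of a reference tree
#'
#' Terminal edges get their tip's taxopath; internal edges (and the root
#' edge, if numbered) get the longest common prefix of the taxopaths of
#' the tips below them.
#'
#' @param tree An `edge_tree`.
#' @param tip_taxopaths Named character vector: tip label -> taxopath
#'   string.
#' @return Named list: edge number (as character) -> rank vector (may be
#'   empty for edges whose tips share no prefix).
#' @export
edge_taxopaths_from_tree <- function(tree, tip_taxopaths) {
  phy <- tree$phylo
  miss <- setdiff(phy$tip.label, names(tip_taxopaths))
  if (length(miss) > 0L) {
    value_error(sprintf("no taxopath for tip '%s'", miss[[1]]))
  }
  nums <- edge_numbers(tree)
  out <- lapply(nums, function(e) {
    sub <- subtree_edge_numbers(tree, e)
    rows <- match(setdiff(sub, tree$root_edge_num), tree$edge_num)
    children <- phy$edge[rows, 2L]
    tips <- children[children <= length(phy$tip.label)]
    paths <- lapply(tip_taxopaths[phy$tip.label[tips]], as_taxopath)
    if (length(paths) == 1L) paths[[1]] else taxopath_lcp(paths)
  })
  names(out) <- as.character(nums)
  out
}

#' Placement-based taxonomic assignment and profile
#'
#' Assigns each pquery the deepest taxopath prefix that accumulates at
#' least `threshold` of its LWR mass: every placement contributes its LWR
#' to all prefixes of its edge's taxopath, and the deepest prefix reaching
#' the threshold wins (ties broken lexicographically). If no prefix
#' qualifies the query is assigned at the root level (empty path). The
#' profile aggregates multiplicities per assigned path.
#'
#' @param doc A `placement_doc`.
#' @param edge_taxopaths Named list edge number -> rank vector, see
#'   [edge_taxopaths_from_tree()].
#' @param threshold Minimum accumulated LWR mass, in `(0, 1]`.
#' @return List with `assignments` (data frame `name`, `multiplicity`,
#'   `assignment`, `depth`) and `profile` (data frame `assignment`,
#'   `mass`, multiplicity-weighted).
#' @export
assign_taxonomy <- function(doc, edge_taxopaths, threshold = 0.66) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    value_error("threshold must lie in (0, 1]")
  }
  rows <- lapply(doc$pqueries, function(pq) {
    pl <- pq$placements
    mass <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(pl))) {
      path <- edge_taxopaths[[as.character(pl$edge_num[[i]])]]
      if (is.null(path)) {
        value_error(sprintf("no taxopath for edge %d", pl$edge_num[[i]]))
      }
      for (k in seq_along(path)) {
        key <- taxopath_string(path[seq_len(k)])
        mass[[key]] <- (if (is.null(mass[[key]])) 0 else mass[[key]]) +
          pl$like_weight_ratio[[i]]
      }
    }
    keys <- ls(mass)
    vals <- vapply(keys, function(k) mass[[k]], numeric(1))
    ok <- keys[vals >= threshold - 1e-12]
    assignment <- ""
    if (length(ok) > 0L) {
      depth <- lengths(strsplit(ok, ";", fixed = TRUE))
      ok <- ok[order(-depth, ok)]
      assignment <- ok[[1]]
    }
    data.frame(
      name = pq$names$name,
      multiplicity = pq$names$multiplicity,
      assignment = assignment,
      depth = if (nzchar(assignment)) length(as_taxopath(assignment)) else 0L,
      stringsAsFactors = FALSE
    )
  })
  assignments <- do.call(rbind, rows)
  profile <- aggregate(
    list(mass = assignments$multiplicity),
    by = list(assignment = assignments$assignment),
    FUN = sum
  )
  list(assignments = assignments, profile = profile)
}

#' Per-query distance report with cumulative curves
#'
#' Computes, for every pquery, the LWR-weighted topological and
#' branch-length distances to its expected edge and its EDPL, plus
#' multiplicity-weighted aggregates: mean distances, the fraction placed
#' exactly on the expected edge (weighted topological distance 0) and
#' within one branch, and cumulative frequency curves of queries versus
#' distance (non-decreasing, ending at 1).
#'
#' @param doc A `placement_doc`.
#' @param expected Named integer vector: query name -> expected edge
#'   number (`NA` entries are counted as unmapped and excluded).
#' @param tree The `edge_tree` the placements refer to.
#' @return An object of class `distance_report`: list with `per_pquery`
#'   (data frame `name`, `multiplicity`, `topo`, `bl`, `edpl`), `summary`
#'   (list `mean_topo`, `mean_bl`, `mean_edpl`, `frac_exact`,
#'   `frac_within_one`, `n_unmapped`) and `curves` (list of data frames
#'   `distance`, `cum_freq` for `topo` and `bl`).
#' @export
distance_report <- function(doc, expected, tree) {
  rows <- list()
  n_unmapped <- 0L
  for (pq in doc$pqueries) {
    name <- pq$names$name[[1]]
    exp_edge <- if (name %in% names(expected)) expected[[name]] else NA_integer_
    if (is.na(exp_edge)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    d <- weighted_distance(pq, exp_edge, tree)
    rows[[length(rows) + 1L]] <- data.frame(
      name = name,
      multiplicity = sum(pq$names$multiplicity),
      topo = d[["topo"]], bl = d[["bl"]],
      edpl = edpl(pq, tree),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) value_error("no mappable pqueries")
  per <- do.call(rbind, rows)
  w <- per$multiplicity
  curve <- function(d) {
    o <- order(d)
    cum <- cumsum(w[o]) / sum(w)
    df <- data.frame(distance = d[o], cum_freq = cum)
    # collapse ties on distance, keeping the final cumulative value
    df[!duplicated(df$distance, fromLast = TRUE), , drop = FALSE]
  }
  structure(
    list(
      per_pquery = per,
      summary = list(
        mean_topo = sum(w * per$topo) / sum(w),
        mean_bl = sum(w * per$bl) / sum(w),
        mean_edpl = sum(w * per$edpl) / sum(w),
        frac_exact = sum(w[per$topo == 0]) / sum(w),
        frac_within_one = sum(w[per$topo <= 1]) / sum(w),
        n_unmapped = n_unmapped
      ),
      curves = list(topo = curve(per$topo), bl = curve(per$bl))
    ),
    class = "distance_report"
  )
}

#' @export
print.distance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<distance_report: %d pqueries (%d unmapped)\n",
      "  mean topo %.4f branches, mean bl %.4f, mean EDPL %.4f\n",
      "  exact %.1f%%, within one branch %.1f%%>\n"
    ),
    nrow(x$per_pquery), s$n_unmapped,
    s$mean_topo, s$mean_bl, s$mean_edpl,
    100 * s$frac_exact, 100 * s$frac_within_one
  ))
  invisible(x)
}
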