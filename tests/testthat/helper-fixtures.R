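# Shared test helpers: tiny trees, independent oracles and random
# generators. The oracles deliberately re-derive results with the
# simplest possible algorithm (full recomputation, explicit BFS) so that
# they stay independent of the implementation paths they check.

# A fixed 4-tip tree with two cherries; 6 numbered edges, no root edge.
balanced4 <- function() {
  parse_edge_newick(
    "((A:0.1{0},B:0.2{1}):0.3{2},(C:0.1{3},D:0.1{4}):0.2{5});"
  )
}

# Random edge-numbered tree: ape topology, edge numbers 0..E-1 in row
# order.
random_edge_tree <- function(n_tips, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_tips, br = function(n) runif(n, 0.05, 1))
  structure(
    list(
      phylo = phy,
      edge_num = seq_len(nrow(phy$edge)) - 1L,
      root_edge_num = NA_integer_
    ),
    class = "edge_tree"
  )
}

# Independent BFS oracle for the topological distance between two edges:
# explicit adjacency matrix (edges sharing a node) and a queue.
oracle_topo_distance <- function(tree, from, to) {
  edge <- tree$phylo$edge
  nums <- tree$edge_num
  k <- nrow(edge)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      adj[i, j] <- i != j && length(intersect(edge[i, ], edge[j, ])) > 0L
    }
  }
  src <- match(from, nums)
  dst <- match(to, nums)
  dist <- rep(NA_integer_, k)
  dist[src] <- 0L
  queue <- src
  while (length(queue) > 0L) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (nb in which(adj[cur, ] & is.na(dist))) {
      dist[nb] <- dist[cur] + 1L
      queue <- c(queue, nb)
    }
  }
  dist[dst]
}

# Random toy taxonomy (< 50 clades) with a random alignment: paths of
# depth 1..3 over a small label pool, sequences attached at full paths.
random_taxonomy_case <- function(seed, n_seqs = 24L, aln_len = 40L) {
  set.seed(seed)
  paths <- vapply(seq_len(n_seqs), function(i) {
    depth <- sample(1:3, 1L)
    paste(
      vapply(seq_len(depth), function(d) {
        sprintf("L%d_%d", d, sample.int(3L, 1L))
      }, character(1)),
      collapse = ";"
    )
  }, character(1))
  assignments <- data.frame(
    seq_id = sprintf("s%02d", seq_len(n_seqs)),
    taxopath = paths,
    stringsAsFactors = FALSE
  )
  aln <- matrix(
    sample(c("A", "C", "G", "T", "-"), n_seqs * aln_len,
           replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
    nrow = n_seqs,
    dimnames = list(assignments$seq_id, NULL)
  )
  list(taxonomy = build_taxonomy(assignments), alignment = aln)
}

# From-scratch greedy expansion oracle: recomputes every candidate's
# entropy each round (no memoization), same leaf rule and lexicographic
# tie-break as documented.
oracle_expand <- function(tax, aln, target) {
  gather <- function(id) {
    c(tax$seq_ids[[id]],
      unlist(lapply(tax$children[[id]], gather), use.names = FALSE))
  }
  entropy_of <- function(id) {
    ids <- gather(id)
    if (length(ids) == 0L) 0 else set_entropy(aln[ids, , drop = FALSE])$total
  }
  cand <- which(tax$parent == 0L)
  count <- length(cand)
  log <- character()
  while (count < target) {
    expandable <- cand[lengths(tax$children[cand]) > 0L]
    if (length(expandable) == 0L) break
    h <- vapply(expandable, entropy_of, numeric(1))
    tied <- expandable[h == max(h)]
    best <- tied[order(tax$path[tied])][[1]]
    cand <- c(cand[cand != best], tax$children[[best]])
    count <- count - 1L + length(tax$children[[best]])
    log <- c(log, tax$path[[best]])
  }
  list(paths = sort(tax$path[cand]), count = count, log = log)
}

# Semantic equality of two placement documents.
expect_docs_equal <- function(a, b, tol = 1e-9) {
  expect_identical(write_edge_newick(a$tree), write_edge_newick(b$tree))
  expect_identical(a$fields, b$fields)
  expect_identical(a$version, b$version)
  expect_equal(length(a$pqueries), length(b$pqueries))
  for (i in seq_along(a$pqueries)) {
    expect_equal(a$pqueries[[i]]$names, b$pqueries[[i]]$names,
                 tolerance = tol, ignore_attr = TRUE)
    expect_equal(a$pqueries[[i]]$placements, b$pqueries[[i]]$placements,
                 tolerance = tol, ignore_attr = TRUE)
  }
}

# Mock "identity" placement engine for preprocessing round trips: places
# every chunk sequence with LWR 1 on a deterministic edge of the tree.
mock_place_chunk <- function(chunk, tree) {
  nums <- sort(edge_numbers(tree))
  pqueries <- lapply(seq_along(chunk), function(i) {
    e <- nums[[(i - 1L) %% length(nums) + 1L]]
    list(
      names = data.frame(name = names(chunk)[[i]], multiplicity = 1,
                         stringsAsFactors = FALSE),
      placements = data.frame(
        edge_num = e, likelihood = -1000, like_weight_ratio = 1,
        distal_length = 0, pendant_length = 0.01
      )
    )
  })
  placement_document(tree, pqueries)
}
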