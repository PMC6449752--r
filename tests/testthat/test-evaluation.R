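test_that("expected edges follow the longest taxopath prefix", {
  tree <- parse_edge_newick(
    "((A.B:1{0},A.B.C:1{1}):1{2},X:1{3});"
  )
  refs <- data.frame(
    taxopath = c("A;B", "A;B;C"),
    label = c("A.B", "A.B.C"),
    stringsAsFactors = FALSE
  )
  expect_identical(expected_edge("A;B;C;D", refs, tree), 1L)
  expect_identical(expected_edge("A;B", refs, tree), 0L)
  expect_identical(expected_edge("A;B;Z", refs, tree), 0L)
  expect_identical(expected_edge("Q", refs, tree), NA_integer_)
})

test_that("edge distances match hand-constructed cases", {
  tri <- parse_edge_newick("((A:0.1{0},B:0.1{1}):0.3{2},C:0.2{3});")
  expect_equal(edge_distances(tri, 0L, 0L), c(topo = 0, bl = 0))
  # attachment at the child (tip) end of edge 0: traverse it fully
  d <- edge_distances(tri, 0L, 1L, distal = 0)
  expect_equal(d, c(topo = 1, bl = 0.1))
  # attachment already at the shared node
  expect_equal(edge_distances(tri, 0L, 1L, distal = 0.1)[["bl"]], 0)
  # cherry tip to the far tip of a balanced 4-tip tree
  tree <- balanced4()
  expect_equal(edge_distances(tree, 0L, 3L)[["topo"]], 3)
  expect_equal(edge_distances(tree, 0L, 3L)[["bl"]], 0.5)
  expect_error(edge_distances(tree, 0L, 99L), class = "phatr_validation_error")
})

test_that("topological distances agree with a BFS oracle on random trees", {
  for (seed in 1:12) {
    tree <- random_edge_tree(sample(4:12, 1L), seed)
    nums <- edge_numbers(tree)
    for (e1 in nums) {
      d_all <- phatr:::edge_topo_distances(tree, e1)
      for (e2 in nums) {
        expect_identical(
          as.integer(d_all[[as.character(e2)]]),
          oracle_topo_distance(tree, e1, e2)
        )
      }
    }
  }
})

test_that("weighted distances are LWR-weighted means and convex", {
  tree <- balanced4()
  pq <- function(edges, lwrs, distal = rep(0, length(edges))) {
    list(
      names = data.frame(name = "q", multiplicity = 1),
      placements = data.frame(
        edge_num = edges, likelihood = -1, like_weight_ratio = lwrs,
        distal_length = distal, pendant_length = 0
      )
    )
  }
  # single placement on the expected edge
  expect_equal(weighted_distance(pq(0L, 1), 0L, tree), c(topo = 0, bl = 0))
  # 0.7 at distance 0 + 0.3 at distance 1
  expect_equal(weighted_distance(pq(c(0L, 1L), c(0.7, 0.3)), 0L, tree)[["topo"]], 0.3)
  # uniform over edges all at distance 2 from edge 0: {1 shares node, ...}
  d_all <- phatr:::edge_topo_distances(tree, 0L)
  at2 <- as.integer(names(d_all)[d_all == 2])
  k <- length(at2)
  expect_equal(
    weighted_distance(pq(at2, rep(1 / k, k)), 0L, tree)[["topo"]], 2
  )
  # convexity: weighted distance between per-placement min and max
  set.seed(3)
  for (i in 1:10) {
    edges <- sample(edge_numbers(tree), 3)
    lwrs <- runif(3); lwrs <- lwrs / sum(lwrs)
    w <- weighted_distance(pq(edges, lwrs), 5L, tree)
    singles <- vapply(edges, function(e) {
      weighted_distance(pq(e, 1), 5L, tree)[["topo"]]
    }, numeric(1))
    expect_gte(w[["topo"]], min(singles))
    expect_lte(w[["topo"]], max(singles))
  }
  expect_error(weighted_distance(pq(0L, 0), 0L, tree),
               class = "phatr_value_error")
})

test_that("EDPL matches hand-computed cases and is relabeling-invariant", {
  # two placements, mass 0.5 each, attachment points 0.4 apart
  tree <- parse_edge_newick("((A:0.5{0},B:0.5{1}):0.5{2},C:0.5{3});")
  pq2 <- list(
    names = data.frame(name = "q", multiplicity = 1),
    placements = data.frame(
      edge_num = c(0L, 1L), likelihood = -1,
      like_weight_ratio = c(0.5, 0.5),
      # distal from child: 0.1 + 0.3 to the shared node = 0.4 apart
      distal_length = c(0.4, 0.2), pendant_length = 0
    )
  )
  expect_equal(edpl(pq2, tree), 0.2)
  # three equiprobable placements mutually 0.3 apart (star tips)
  star <- parse_edge_newick("(A:0.15{0},B:0.15{1},C:0.15{2});")
  pq3 <- list(
    names = data.frame(name = "q", multiplicity = 1),
    placements = data.frame(
      edge_num = 0:2, likelihood = -1, like_weight_ratio = rep(1 / 3, 3),
      distal_length = 0, pendant_length = 0
    )
  )
  expect_equal(edpl(pq3, tree = star), 0.2)
  # single placement
  pq1 <- list(
    names = data.frame(name = "q", multiplicity = 1),
    placements = data.frame(
      edge_num = 0L, likelihood = -1, like_weight_ratio = 0.8,
      distal_length = 0.1, pendant_length = 0
    )
  )
  expect_identical(edpl(pq1, tree), 0)
  # permuting the placement rows leaves EDPL unchanged
  perm <- pq2
  perm$placements <- perm$placements[2:1, ]
  expect_equal(edpl(perm, tree), edpl(pq2, tree))
  # all mass at one attachment point (same edge, same distal) -> 0
  same <- pq2
  same$placements$edge_num <- c(0L, 0L)
  same$placements$distal_length <- c(0.25, 0.25)
  expect_equal(edpl(same, tree), 0)
})

test_that("clade accuracy counts best hits on correctly labeled edges", {
  tree <- balanced4()
  assoc <- clade_association(tree, c(0L, 1L, 3L, 4L),
                             c("ct1", "ct1", "ct2", "ct2"))
  mk <- function(name, edges, lwrs) list(
    names = data.frame(name = name, multiplicity = 1),
    placements = data.frame(
      edge_num = edges, likelihood = -1, like_weight_ratio = lwrs,
      distal_length = 0, pendant_length = 0
    )
  )
  doc <- placement_document(tree, list(
    mk("a", 0L, 1), mk("b", 1L, 1), mk("c", 3L, 1), mk("d", 3L, 1)
  ))
  truth <- c(a = "ct1", b = "ct1", c = "ct2", d = "ct1")  # d misrouted
  acc <- clade_accuracy(doc, assoc, truth)
  expect_equal(acc$overall, 0.75)
  expect_equal(acc$per_label$accuracy[acc$per_label$label == "ct2"], 1.0)
  # overlap: best hit on either ct1 edge counts
  doc2 <- placement_document(tree, list(mk("a", c(1L, 0L), c(0.9, 0.1))))
  expect_equal(clade_accuracy(doc2, assoc, truth["a"])$overall, 1.0)
  expect_error(clade_accuracy(doc, assoc, truth[1:3]),
               class = "phatr_value_error")
})

test_that("taxonomic assignment takes the deepest prefix above threshold", {
  tree <- parse_edge_newick("((T1:1{0},T2:1{1}):1{2},T3:1{3});")
  paths <- c(T1 = "A;B;X", T2 = "A;B;Y", T3 = "Q")
  etp <- edge_taxopaths_from_tree(tree, paths)
  expect_identical(etp[["0"]], c("A", "B", "X"))
  expect_identical(etp[["2"]], c("A", "B"))
  mk <- function(edges, lwrs) placement_document(tree, list(list(
    names = data.frame(name = "q", multiplicity = 2),
    placements = data.frame(
      edge_num = edges, likelihood = -1, like_weight_ratio = lwrs,
      distal_length = 0, pendant_length = 0
    )
  )))
  # full mass on one tip: its whole path
  a1 <- assign_taxonomy(mk(0L, 1), etp)
  expect_identical(a1$assignments$assignment, "A;B;X")
  # split across the cherry: shared prefix A;B at threshold 0.66
  a2 <- assign_taxonomy(mk(c(0L, 1L), c(0.5, 0.5)), etp)
  expect_identical(a2$assignments$assignment, "A;B")
  # mass scattered below threshold everywhere: root-level assignment
  a3 <- assign_taxonomy(mk(c(0L, 3L), c(0.5, 0.5)), etp)
  expect_identical(a3$assignments$assignment, "")
  expect_identical(a3$assignments$depth, 0L)
  # profile is multiplicity-weighted
  expect_equal(a2$profile$mass[a2$profile$assignment == "A;B"], 2)
  expect_error(assign_taxonomy(mk(0L, 1), etp, threshold = 0),
               class = "phatr_value_error")
  expect_error(assign_taxonomy(mk(0L, 1), etp, threshold = 1.2),
               class = "phatr_value_error")
})

test_that("distance reports recover planted noise radii", {
  for (r in 0:2) {
    tree <- random_edge_tree(10, seed = 100 + r)
    nums <- edge_numbers(tree)
    set.seed(50 + r)
    truth <- setNames(sample(nums, 30, replace = TRUE), sprintf("q%d", 1:30))
    doc <- make_mock_jplace(tree, truth, noise_radius = r, lwr_alpha = 3,
                            seed = 7)
    rep <- distance_report(doc, truth, tree)
    curve <- rep$curves$topo
    expect_true(all(diff(curve$cum_freq) >= 0))
    expect_equal(curve$cum_freq[[nrow(curve)]], 1.0)
    expect_lte(max(curve$distance), r)
    if (r == 0) {
      expect_equal(rep$summary$frac_exact, 1.0)
      expect_equal(rep$summary$mean_bl, 0)
      expect_true(all(rep$per_pquery$edpl == 0))
    }
  }
})

test_that("unmapped queries are excluded but counted", {
  tree <- balanced4()
  truth <- c(q1 = 0L, q2 = NA_integer_)
  doc <- make_mock_jplace(tree, c(q1 = 0L, q2 = 1L), noise_radius = 0L)
  rep <- distance_report(doc, truth, tree)
  expect_identical(rep$summary$n_unmapped, 1L)
  expect_identical(nrow(rep$per_pquery), 1L)
})
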