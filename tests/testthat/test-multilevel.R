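make_doc <- function(tree, specs) {
  # specs: list of list(name, mult, edges, lwrs)
  pqs <- lapply(specs, function(s) {
    list(
      names = data.frame(name = s$name, multiplicity = s$mult,
                         stringsAsFactors = FALSE),
      placements = data.frame(
        edge_num = s$edges, likelihood = -1,
        like_weight_ratio = s$lwrs, distal_length = 0, pendant_length = 0
      )
    )
  })
  placement_document(tree, pqs)
}

test_that("best-hit routing sends queries to clades and filters inner hits", {
  tree <- balanced4()
  assoc <- clade_association(tree, c(0L, 1L, 3L, 4L),
                             c("ct1", "ct1", "ct2", "ct2"))
  doc <- make_doc(tree, list(
    list(name = "A", mult = 2, edges = c(0L, 2L), lwrs = c(0.8, 0.2)),
    list(name = "B", mult = 1, edges = c(2L, 0L), lwrs = c(0.9, 0.1)),
    list(name = "C", mult = 3, edges = 4L, lwrs = 1.0)
  ))
  r <- route(doc, assoc)
  expect_identical(r$routed$ct1$name, "A")
  expect_identical(r$routed$ct2$name, "C")
  expect_identical(r$filtered$name, "B")
  # abundance conservation
  total <- sum(vapply(r$routed, function(df) sum(df$multiplicity), numeric(1))) +
    sum(r$filtered$multiplicity)
  expect_equal(total, 6)
})

test_that("mass-threshold routing accumulates LWR over a clade's edges", {
  tree <- balanced4()
  assoc <- clade_association(tree, c(0L, 1L, 3L, 4L),
                             c("ct1", "ct1", "ct2", "ct2"))
  doc <- make_doc(tree, list(
    # 0.6 + 0.4 both on ct1 edges: accumulates to 1.0
    list(name = "q", mult = 1, edges = c(0L, 1L), lwrs = c(0.6, 0.4)),
    # 0.45 on each clade: reaches neither at 0.5... except threshold 0.4
    list(name = "r", mult = 1, edges = c(0L, 3L), lwrs = c(0.45, 0.45))
  ))
  r1 <- route(doc, assoc, mode = "mass_threshold", threshold = 1.0)
  expect_identical(r1$routed$ct1$name, "q")
  expect_identical(r1$filtered$name, "r")
  r2 <- route(doc, assoc, mode = "mass_threshold", threshold = 0.4)
  expect_identical(r2$routed$ct1$name, c("q", "r"))
  expect_identical(r2$routed$ct2$name, "r")   # multi-routing
  # best_hit also routes q to ct1
  expect_identical(route(doc, assoc)$routed$ct1$name[[1]], "q")
})

test_that("best-hit routing ignores placement order", {
  tree <- balanced4()
  assoc <- clade_association(tree, c(0L, 1L), c("ct1", "ct1"))
  base <- list(name = "q", mult = 1, edges = c(0L, 2L, 5L),
               lwrs = c(0.5, 0.3, 0.2))
  r0 <- route(make_doc(tree, list(base)), assoc)
  for (i in 1:4) {
    perm <- sample(3)
    doc <- make_doc(tree, list(modifyList(base, list(
      edges = base$edges[perm], lwrs = base$lwrs[perm]
    ))))
    r <- route(doc, assoc)
    expect_identical(r$routed$ct1$name, r0$routed$ct1$name)
  }
})

test_that("uniform labels route everything and filter nothing", {
  tree <- balanced4()
  assoc <- clade_association(tree, edge_numbers(tree),
                             rep("all", length(edge_numbers(tree))))
  doc <- make_doc(tree, list(
    list(name = "a", mult = 2, edges = 2L, lwrs = 1),
    list(name = "b", mult = 5, edges = 5L, lwrs = 1)
  ))
  r <- route(doc, assoc)
  expect_identical(nrow(r$filtered), 0L)
  expect_setequal(r$routed$all$name, c("a", "b"))
  expect_equal(sum(r$routed$all$multiplicity), 7)
})

test_that("monophyly detection matches an exhaustive split check", {
  # 6-tip caterpillar-ish tree
  tree <- parse_edge_newick(paste0(
    "((A:1{0},B:1{1}):1{2},((C:1{3},D:1{4}):1{5},(E:1{6},F:1{7}):1{8}):1{9});"
  ))
  mono <- function(edges, labels) {
    check_monophyly(tree, clade_association(tree, edges, labels), labels[[1]])
  }
  # full cherry subtree including its stem edge
  r <- mono(c(3L, 4L, 5L), rep("x", 3))
  expect_true(r$monophyletic)
  # strictly-below variant: the two cherry edges, split = their stem
  r2 <- mono(c(3L, 4L), rep("x", 2))
  expect_true(r2$monophyletic)
  expect_identical(r2$edge, 5L)
  # single terminal edge
  r3 <- mono(6L, "x")
  expect_true(r3$monophyletic)
  # two edges in disjoint subtrees: no single split separates them
  r4 <- mono(c(0L, 6L), rep("x", 2))
  expect_false(r4$monophyletic)
  # oracle: brute-force over all edges, both separation readings
  brute <- function(edges) {
    any(vapply(edge_numbers(tree), function(e) {
      below <- phatr:::subtree_edge_numbers(tree, e)
      setequal(below, edges) || setequal(setdiff(below, e), edges)
    }, logical(1)))
  }
  set.seed(42)
  for (i in 1:20) {
    k <- sample(1:5, 1L)
    edges <- sample(edge_numbers(tree), k)
    got <- mono(edges, rep("x", k))$monophyletic
    expect_identical(got, brute(edges))
  }
})

test_that("the cost model reproduces the canonical split example", {
  cm <- cost_model(10000, 1000, 1000)
  expect_equal(cm$speedup, 5.0)
  expect_equal(cm$memory_factor, 10.0)
  # no benefit when the two levels jointly equal the full tree
  cm2 <- cost_model(1000, 500, 500)
  expect_equal(cm2$speedup, 1.0)
  expect_error(cost_model(0, 1, 1), class = "phatr_value_error")
})

test_that("clade associations resolve from taxopath prefixes", {
  tx <- build_taxonomy(data.frame(
    seq_id = c("1", "2", "3", "4"),
    taxopath = c("A;B", "A;C", "D;E", "D;F")
  ))
  aln <- alignment_matrix(setNames(c("AAAA", "CCCC", "GGGG", "TTTT"),
                                   c("1", "2", "3", "4")))
  cs <- expand_taxonomy(tx, aln, 4)
  refs <- build_reference_set(cs, tx, aln)
  # tree over the sanitized labels
  tree <- parse_edge_newick(
    "((A.B:1{0},A.C:1{1}):1{2},(D.E:1{3},D.F:1{4}):1{5});"
  )
  assoc <- clade_association_from_paths(tree, c(ctA = "A", ctD = "D"))
  expect_identical(unname(assoc$mapping[c("0", "1")]), rep("ctA", 2))
  expect_identical(unname(assoc$mapping[c("3", "4")]), rep("ctD", 2))
  expect_identical(unname(assoc$mapping[c("2", "5")]), rep("inner", 2))
})
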