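test_that("expansion with target equal to the initial count is a no-op", {
  case <- random_taxonomy_case(1)
  roots <- taxonomy_roots(case$taxonomy)
  cs <- expand_taxonomy(case$taxonomy, case$alignment, length(roots))
  expect_identical(cs$candidates, roots)
  expect_identical(cs$expansion_log, character())
  expect_identical(cs$taxa_count, length(roots))
  expect_identical(cs$deviation_pct, 0)
})

test_that("the most diverse clade is expanded first (hand-executed toy)", {
  # X: three children, internally diverse; Y: a homogeneous leaf clade.
  df <- data.frame(
    seq_id = c("x1", "x2", "x3", "y1", "y2"),
    taxopath = c("X;X1", "X;X2", "X;X3", "Y", "Y")
  )
  tx <- build_taxonomy(df)
  aln <- alignment_matrix(c(
    x1 = "AAAAAAAA", x2 = "CCCCCCCC", x3 = "GGGGGGGG",
    y1 = "TTTTTTTT", y2 = "TTTTTTTT"
  ))
  cs <- expand_taxonomy(tx, aln, 4)
  expect_identical(cs$expansion_log, "X")
  expect_setequal(cs$paths, c("X;X1", "X;X2", "X;X3", "Y"))
  expect_identical(cs$taxa_count, 4L)
})

test_that("bookkeeping identity holds for every expansion step", {
  case <- random_taxonomy_case(3)
  tx <- case$taxonomy
  cs <- expand_taxonomy(tx, case$alignment, 20)
  count <- length(taxonomy_roots(tx))
  for (p in cs$expansion_log) {
    kids <- tx$children[[clade_id(tx, p)]]
    expect_gte(length(kids), 1L)
    count <- count - 1L + length(kids)
  }
  expect_identical(count, cs$taxa_count)
  expect_identical(count, length(cs$candidates))
})

test_that("expansion terminates on all-leaf candidates without meeting the target", {
  tx <- build_taxonomy(data.frame(
    seq_id = c("a", "b", "c"), taxopath = c("A", "B", "C")
  ))
  aln <- alignment_matrix(c(a = "ACGT", b = "AAAA", c = "TTTT"))
  cs <- expand_taxonomy(tx, aln, 10)
  expect_identical(cs$taxa_count, 3L)
  expect_identical(cs$expansion_log, character())
  expect_equal(cs$deviation_pct, 70)
})

test_that("target below the initial candidate count is a value error", {
  case <- random_taxonomy_case(2)
  expect_error(
    expand_taxonomy(case$taxonomy, case$alignment,
                    length(taxonomy_roots(case$taxonomy)) - 1L),
    class = "phatr_value_error"
  )
})

test_that("expansion agrees with a from-scratch greedy oracle", {
  for (seed in 1:30) {
    case <- random_taxonomy_case(seed)
    target <- sample(2:20, 1L)
    target <- max(target, length(taxonomy_roots(case$taxonomy)))
    got <- expand_taxonomy(case$taxonomy, case$alignment, target)
    want <- oracle_expand(case$taxonomy, case$alignment, target)
    expect_identical(sort(got$paths), want$paths)
    expect_identical(got$expansion_log, want$log)
    expect_identical(got$taxa_count, want$count)
  }
})

test_that("equal entropies expand in lexicographic path order", {
  # zero divergence -> all clade entropies 0 -> pure tie-breaking
  fx <- make_taxonomy_and_alignment(fixture_config(seed = 2, divergence = 0))
  cs <- expand_taxonomy(fx$taxonomy, fx$alignment, 5)
  expect_identical(cs$expansion_log, "C1")
  cs2 <- expand_taxonomy(fx$taxonomy, fx$alignment, 9)
  expect_identical(cs2$expansion_log[1:2], c("C1", "C1;C1.1"))
})

test_that("reference sets carry consensus sequences and distinct labels", {
  fx <- make_taxonomy_and_alignment(fixture_config(seed = 4))
  cs <- expand_taxonomy(fx$taxonomy, fx$alignment, 5)
  refs <- build_reference_set(cs, fx$taxonomy, fx$alignment)
  expect_identical(nrow(refs), 5L)
  expect_false(anyDuplicated(refs$label) > 0)
  expect_true(all(nchar(refs$sequence) == ncol(fx$alignment)))
  expect_identical(sum(refs$n_sequences), nrow(fx$alignment))

  # a single-sequence candidate reproduces its sequence
  tx <- build_taxonomy(data.frame(seq_id = "s", taxopath = "A"))
  aln <- alignment_matrix(c(s = "ACG-T"))
  one <- expand_taxonomy(tx, aln, 1)
  rec <- build_reference_set(one, tx, aln)
  expect_identical(rec$sequence, "ACG-T")

  # the "first sequence" baseline picks a database sequence verbatim
  refs_first <- build_reference_set(cs, fx$taxonomy, fx$alignment, method = "first")
  expect_true(all(
    vapply(seq_len(nrow(refs_first)), function(i) {
      ids <- clade_sequences(fx$taxonomy, refs_first$taxopath[[i]])
      refs_first$sequence[[i]] %in%
        apply(fx$alignment[ids, , drop = FALSE], 1, paste, collapse = "")
    }, logical(1))
  ))
})

test_that("constraint trees mirror the taxonomy restricted to candidates", {
  tx <- build_taxonomy(data.frame(
    seq_id = c("1", "2", "3"), taxopath = c("A;B", "A;C", "D")
  ))
  aln <- alignment_matrix(setNames(rep("ACGT", 3), c("1", "2", "3")))
  cs <- expand_taxonomy(tx, aln, 3)
  nwk <- build_constraint_tree(cs, tx)
  expect_identical(nwk, "((A.B,A.C),D);")
  # labels round-trip through a newick reader
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A.B", "A.C", "D"))

  # all candidates under one root give a single multifurcation
  tx2 <- build_taxonomy(data.frame(
    seq_id = c("1", "2", "3"), taxopath = c("A;B", "A;C", "A;D")
  ))
  cs2 <- expand_taxonomy(tx2, aln, 3)
  expect_identical(build_constraint_tree(cs2, tx2), "(A.B,A.C,A.D);")
  # single candidate is an error
  one <- expand_taxonomy(tx2, aln, 1)
  expect_error(build_constraint_tree(one, tx2), class = "phatr_value_error")
})

test_that("planted diverse clades are expanded before homogeneous ones", {
  cfg <- fixture_config(seed = 8, divergence = 0.01,
                        diverse_clades = "C3", diverse_rate = 0.4)
  fx <- make_taxonomy_and_alignment(cfg)
  cs <- expand_taxonomy(fx$taxonomy, fx$alignment, 5)
  expect_identical(cs$expansion_log[[1]], "C3")
})
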