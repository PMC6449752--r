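---
title: "Methods: entropy-guided reference trees and placement utilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-guided reference trees and placement utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phatr)
```

This vignette documents the models and procedures implemented in `phatr`,
the assumptions behind them, the parameters that matter, and the design
decisions taken where more than one reasonable choice existed.

## Sequence entropy

All selection decisions rest on the Shannon entropy of alignment sites
over the five-state alphabet {A, C, G, T, −}:

$$ H_i = -\sum_{c} f_{c,i} \log_2 f_{c,i}, \qquad H(s) = \sum_i H_i $$

with $0 \log 0 = 0$. Treating the gap as a fifth state is deliberate:
likelihood-based inference treats gaps as undetermined states that
contribute nothing, so sites dominated by gaps carry little signal, and
counting the gap as a state shrinks the entropy contribution of such
sites. Ambiguity codes (N, R, Y, …) are normalized to gaps at read time;
in curated rRNA databases they are too rare to justify fractional
counting, and the package does not offer it. $H_i$ is zero for
single-state sites and maximal, $\log_2 5 \approx 2.32$ bits, when all
five states are equally frequent (20% each) — a property the test suite
verifies against an exhaustive grid search over the frequency simplex.

A reporting-only *normalized* entropy, $H(s) / (L \log_2 5) \in [0, 1]$,
is attached to every entropy profile. This normalization (by the maximum
attainable total for an alignment of length $L$) is this package's own
bounded definition; nothing downstream depends on it.

Degenerate inputs: frequencies must be non-negative and sum to 1 within
$10^{-9}$; an empty sequence set is an error, but a clade whose subtree
holds no sequences has entropy 0 by definition (with a warning) — such a
clade can never be the most diverse candidate, so this choice cannot
influence the expansion path, and empty clades are dropped later at
consensus time.

## Greedy taxonomy expansion

Reference sets are chosen by a greedy loop over a taxonomy in which every
clade knows the sequences attached at itself and in its subtree:

1. Initialize the candidate list with the top-rank clades.
2. While the candidate count is below the target: pick the candidate with
   the highest clade entropy, remove it, add its immediate sub-clades, and
   update the count by $-1 + \text{number of sub-clades}$.

Two details are underdetermined by that sketch and fixed here:

* **Leaf clades are never expanded.** Removing a leaf would silently lose
  its taxa. When the entropy argmax is a leaf it is kept as a candidate
  and the next expandable candidate is taken; the loop also stops when
  every candidate is a leaf, in which case the target cannot be met. The
  relative deviation of the final count from the target is reported
  (`deviation_pct`) so users can see how closely their target was
  realized.
* **Ties break lexicographically** by full taxopath. With equal entropies
  (e.g. a zero-divergence synthetic database) runs are therefore exactly
  reproducible.

Clade entropies are memoized: a clade's sequence set never changes during
expansion, so each entropy is computed once. The test suite checks the
memoized implementation against an oracle that recomputes every candidate
entropy from scratch each round on randomized taxonomies.

Because an expanded clade may have many children, the final count can
overshoot the target; it never undershoots except in the all-leaves case.
Candidates counted include clades whose sequence sets may be empty; they
are dropped (with a warning) when consensus sequences are built, which
keeps the bookkeeping of the expansion loop exact.

## Consensus sequences

Each candidate clade is condensed site-by-site into one sequence:

* `majority` (default): the most frequent of the five states, no quorum.
  This retains a character even at highly diverse sites, maximizing
  signal; it is the method used throughout the package's own pipeline.
* `cavener`: the most frequent state if its frequency exceeds 0.5, else a
  gap. Cavener's original rule also emits two-base ambiguity codes when
  the top two states jointly exceed 0.75 with each above 0.25; collapsed
  onto the five-state alphabet those cases have no representation and
  yield a gap. This collapse is this package's interpretation and is
  selectable, not default.
* `threshold(x)`: the most frequent state if its frequency is at least
  `x`, else a gap.

Frequency ties prefer non-gap over gap, then alphabetical order — biased
toward retaining sequence signal, and deterministic. As a baseline,
`method = "first"` picks the clade's first database sequence verbatim
instead of a consensus; it is provided for comparison only and not tuned.

Tip labels are sanitized taxopaths (ranks joined by `.`, newick-unsafe
characters replaced by `_`); the label-to-path mapping is part of the
reference-set table, and the CLI writes it to a sidecar TSV.

## Constraint trees

`build_constraint_tree()` restricts the taxonomy to the candidate paths,
collapses ranks that do not split the candidates, and emits a
multifurcating newick without branch lengths, with candidates ordered
lexicographically for deterministic output. Used as a topological
constraint in maximum-likelihood inference, it keeps high-level taxonomy
clades monophyletic in the resulting reference tree — which is exactly
what multilevel placement needs from its backbone.

## Multilevel placement

A clade association maps every backbone edge to a clade-tree label or to
`"inner"`. Routing supports two modes:

* `best_hit` (default): a query follows its single highest-LWR placement.
  This matches how "most likely placement" accuracy is conventionally
  assessed, and gives a clean partition of queries into routed and
  filtered sets (abundance is conserved exactly — a tested invariant).
* `mass_threshold(x)` (default `x = 0.5`): a query goes to every clade
  tree whose associated edges accumulate LWR mass at least `x`, so one
  query can legitimately reach several overlapping clade trees.

Which of the two a published pipeline used is typically not stated; both
are provided and `best_hit` is the package default. Queries routed
nowhere are "filtered" — placement-based filtering of spurious reads,
deliberately more permissive than similarity-based filtering.

Monophyly of a label's edge set is accepted under two readings: the set
equals some edge plus everything below it, or exactly everything strictly
below some edge (that edge being the separating split). Both describe "one
split separates these branches"; accepting either avoids an arbitrary
convention about whether the subtending branch belongs to the clade.

The cost model assumes placement cost per query is linear in the number
of reference taxa and that each query is placed once on the backbone and
once on one clade tree; memory is governed by the largest tree held at a
time. These are first-order approximations — alignment length and engine
constants are ignored.

## Preprocessing

Deduplication is exact string identity on uppercased raw reads — no U→T
mapping and no ambiguity handling, since placement engines see the reads
as given; case is folded because it carries no biological meaning.
Unique-sequence identifiers are zero-padded running indices in first-
occurrence order, so a re-run on the same input reproduces the same ids.
Chunks are equally sized except the last (tested load-balance property);
the default chunk size of 50 000 is a practical compromise: chunks must
be large enough to amortize aligner/placer startup, small enough to fit
the intended hardware's wall time. FASTQ qualities are discarded.

Resolution requires all per-chunk placement documents to share one
reference tree (compared semantically: topology, branch lengths, edge
numbers). A sequence placed in two chunks is an error; sequences never
placed are reported as unplaced rather than silently dropped, and the
tested end-to-end invariant is that routed multiplicities plus unplaced
reads equal the input read count exactly.

## Evaluation

Coordinates follow the jplace conventions: edges are identified by edge
number; a placement's `distal_length` is measured from the edge's
child-side node; pendant lengths are off-tree and excluded from all
distances.

* **Topological distance** counts branches: 0 on the same edge, 1 for
  edges sharing a node, else shortest path in the edge adjacency graph
  (verified exhaustively against a brute-force BFS oracle on random small
  trees). "Same edge = 0, adjacent = 1" makes "within one branch of the
  expected edge" well-defined.
* **Branch-length distance** runs from the placement's attachment point to
  the *nearest point* of the expected edge, so a placement anywhere on the
  expected edge scores 0 — placements "exactly on their expected branch"
  are exact hits regardless of position along it.
* **EDPL** is the LWR-weighted mean pairwise branch-length distance
  between a query's attachment points (weights normalized to their sum);
  it is 0 iff all mass sits at one point, and invariant under reordering
  of the placement list.
* **Expected edges** map a query to the terminal edge of the reference
  candidate whose taxopath is the longest prefix of the query's taxopath;
  queries with no prefix match are counted as unmapped and excluded from
  distance statistics.
* **Taxonomic assignment** gives each query the deepest taxopath prefix
  accumulating at least a threshold of its LWR mass. The default
  threshold of 0.66 requires a two-thirds majority — conservative enough
  that at most one path can qualify per depth — and is configurable; no
  canonical value exists for this cutoff.

A root edge (an edge number on the tree's root itself) is supported
throughout: it hangs above the root, its child-side node *is* the root,
and paths leave it only through the root.

## Synthetic data: what it does and does not show

The fixture generator emulates the *shape* of a taxonomically annotated
database: a complete taxonomy of configurable depth and branching, an
independent random ancestral sequence per top clade, per-site uniform
substitution (rate = the clade's divergence) along each parent-to-child
step, attached sequences mutated from the deepest clades' ancestral
sequences, and a fraction of globally shared gap columns. Planting an
elevated divergence in selected top clades makes the entropy argmax known
by construction, so greedy-expansion order, placement-noise recovery and
clade-identification accuracy can be asserted exactly.

It does **not** emulate real rRNA evolution: no substitution-rate
heterogeneity across sites, no indels (gap columns are shared, hence
entropy-free), no base-composition bias, no alignment error, and mock
placements draw LWRs from a gamma scheme (shape `lwr_alpha` on the true
edge, 1 elsewhere, normalized) rather than from a likelihood model.
Passing tests therefore demonstrate algorithmic correctness — orderings,
conservation laws, metric definitions, format round-trips — not the
placement accuracy attainable on real databases, which depends on the
database, the aligner and the placement engine.

Default generator conditions (3 top clades, depth 2, branching 3, 4
sequences per deepest clade, 120 alignment sites, divergence 0.1, 5% gap
columns, 3 samples of 50 reads at 50% duplication) are small enough that
the full suite, including the oracle-equivalence loops (100 random
taxonomies for the greedy oracle, exhaustive edge pairs on trees of up to
12 tips for the BFS oracle), runs in well under a minute.

## File formats and numerical tolerances

jplace version 3 is assumed (the version the surrounding tool ecosystem
emits); other versions are rejected rather than guessed at. Edge numbers
must cover 0..E−1 uniquely. On read, both the standard `{N}` and the
legacy `[N]` edge-number dialects are accepted; writes always emit braces.
The `nm` (name + multiplicity) pquery style is written; bare `n` names are
accepted on read with multiplicity 1. Validation tolerances: LWR sums may
exceed 1 by at most 1e−6, `distal_length` may exceed the branch length by
at most 1e−6 (placement engines emit exactly such rounding slop);
frequency vectors must sum to 1 within 1e−9. Round-trips preserve
semantic content (topology, lengths at 10 significant digits, numbers,
fields, multiplicities), not byte identity.

The command line accepts a YAML config file (flag > config > default
precedence); YAML was chosen as the single config dialect since it is the
one with first-class R support.

## Known limitations

* Tree resolution is bounded by the taxonomy: unexpanded clades are
  represented by a single consensus, which obscures their internal
  diversity — multilevel placement with overlapping clade trees is the
  intended mitigation, not a fix within the reference set itself.
* Consensus sequences inherit database mislabeling; the package does not
  attempt label correction.
* `deduplicate()` holds all unique sequences in memory; at the scale this
  package targets in R (method development, evaluation, moderate studies)
  that is fine, but hundred-million-read studies need streaming tools.
* The maximum-likelihood inference between `build_reference_set()` and
  placement, and the placement engines themselves, are intentionally out
  of scope.
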