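# phatr

Automatic phylogenetic reference trees and utilities for large-scale
phylogenetic placement, in R.

## The problem

Phylogenetic placement attaches environmental query sequences (reads) onto
the branches of a fixed reference tree (RT), scoring every branch by
likelihood. It is the method of choice for identifying reads from
under-explored environments, but three practical bottlenecks limit it:
reference sequences are usually picked by hand; placement cost grows with
both the number of reads and the size of the RT; and trees large enough to
cover the diversity of a metagenomic sample are too large to infer,
visualize and interpret. `phatr` addresses all three for users of
taxonomically annotated rRNA databases (Silva-style alignments with
semicolon-delimited taxonomic paths) and of the jplace placement format.

## What the package computes

**Entropy-guided reference sets.** The Shannon entropy of alignment site
*i* over the five states *c* ∈ {A, C, G, T, −} is

    H_i = − Σ_c f_{c,i} · log2 f_{c,i}

with gaps counted as a fifth state (which down-weights gap-rich sites) and
ambiguity codes normalized to gaps. The entropy of a sequence set is
H(s) = Σ_i H_i, and the entropy H(t) of a taxonomic clade *t* is that of
all sequences in the clade and its sub-clades. Starting from the top-rank
clades, `expand_taxonomy()` greedily replaces the candidate clade with the
highest H(t) by its immediate sub-clades until a user-chosen target count
is reached — diverse clades get split, homogeneous clades get kept whole.
`build_reference_set()` then condenses each surviving clade into one
per-site consensus sequence (majority rule by default), labeled by its
taxonomic path; these consensus sequences are the input for external
maximum-likelihood inference of the RT, optionally constrained by the
taxonomy via `build_constraint_tree()`.

**Multilevel placement.** `route()` implements two-level ("backbone tree
plus clade trees") placement bookkeeping: queries placed on backbone
branches associated with a clade tree are forwarded to it, queries on
unassociated inner branches are filtered out. `check_monophyly()` verifies
that a clade's backbone branches form one split, and `cost_model()` gives
the analytic gains: splitting an *n*-taxon tree into a backbone of *b*
taxa and clade trees of *c* taxa costs *n*/(*b*+*c*) less per query and
*n*/max(*b*, *c*) less memory.

**Preprocessing.** `deduplicate()` collapses exactly identical reads
across samples into uniform chunks with per-sample abundance counts (the
speedup is the total/unique ratio, `dedup_gain()`);
`resolve_placements()` turns per-chunk placement results back into
per-sample jplace documents carrying the original multiplicities.

**Evaluation.** Weighted (by likelihood weight ratio) topological and
branch-length distances to expected edges (`weighted_distance()`,
`distance_report()` with cumulative curves), the expected distance between
placement locations (`edpl()`), clade identification accuracy
(`clade_accuracy()`) and placement-based taxonomic assignment
(`assign_taxonomy()`).

## Worked example

Build a reference set from a synthetic database in which clade `C2` has
planted high diversity:

```r
library(phatr)
fx <- make_taxonomy_and_alignment(
  fixture_config(seed = 42, diverse_clades = "C2", diverse_rate = 0.4)
)
fx$taxonomy
#> <taxonomy: 39 clades (3 top-rank), 108 attached sequences>

cands <- expand_taxonomy(fx$taxonomy, fx$alignment, 5)
cands
#> <candidate_set: 5 candidates (target 5, deviation 0.00%), 1 expansions>
cands$expansion_log
#> [1] "C2"

refs <- build_reference_set(cands, fx$taxonomy, fx$alignment)
refs[, c("taxopath", "label", "n_sequences")]
#>   taxopath   label n_sequences
#> 1       C1      C1          36
#> 2       C3      C3          36
#> 3  C2;C2.1 C2.C2.1          12
#> 4  C2;C2.2 C2.C2.2          12
#> 5  C2;C2.3 C2.C2.3          12

build_constraint_tree(cands, fx$taxonomy)
#> [1] "(C1,(C2.C2.1,C2.C2.2,C2.C2.3),C3);"
```

The greedy loop expanded exactly the planted diverse clade: `C2` was
replaced by its three sub-clades (each summarized by a consensus over its
12 sequences), while the homogeneous `C1` and `C3` stay represented by one
consensus each. The constraint tree keeps the `C2` sub-clades together for
the subsequent tree inference. The analytic gains of splitting a
10000-taxon tree into a 1000-taxon backbone plus 1000-taxon clade trees:

```r
cost_model(10000, 1000, 1000)
#> speedup 5.0, memory factor 10.0
```

The same steps are available from the shell via the bundled wrapper
(`inst/exec/phatr`): `phat`, `entropy`, `route`, `chunkify`, `unchunkify`,
`eval`, `fixtures` and `cost-model` subcommands; see `phatr --help`.

## Scope

The package deliberately does **not** run maximum-likelihood tree
inference, query alignment, or the placement engines themselves; it
prepares their inputs and consumes their outputs. Distance-based
post-analyses such as Edge PCA or Squash Clustering are out of scope.
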