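# Synthetic data generation.
#
# Every module of the package is testable without a database download:
# this module generates toy taxonomies with evolved alignments (controlled
# per-clade divergence so that entropy orderings are known by
# construction), multi-sample read sets with duplicates, and mock
# placement documents with planted truth. The mutation model is
# deliberately simple — per-site uniform substitution among the other
# three nucleotides, plus globally shared gap columns — which is
# sufficient to drive entropy-based decisions but does not emulate real
# rRNA evolution (no rate heterogeneity, no indels, no base composition
# bias).

#' Configuration for synthetic fixtures
#'
#' @param seed Integer seed; the same seed yields identical fixtures.
#' @param depth Number of taxonomy ranks below the top rank.
#' @param branching Children per internal taxonomy clade.
#' @param n_per_clade Sequences attached at each deepest-rank clade.
#' @param aln_length Alignment length in sites.
#' @param divergence Per-site substitution probability applied on every
#'   parent-to-child step and when sampling attached sequences; 0 makes
#'   all sequences of a top clade identical.
#' @param gap_fraction Fraction of alignment columns turned into all-gap
#'   columns (shared across sequences, so they add no entropy).
#' @param diverse_clades Character vector of top-rank clade names whose
#'   subtrees use `diverse_rate` instead of `divergence` (planted
#'   diversity with a known entropy argmax).
#' @param diverse_rate Substitution probability for `diverse_clades`.
#' @param n_samples,reads_per_sample Shape of generated read sets.
#' @param dup_rate Fraction of reads that are duplicates of earlier reads
#'   (controls the unique/total ratio).
#' @param noise_radius Topological radius (in branches) of mock placement
#'   noise around the true edge.
#' @param lwr_alpha Concentration of the LWR distribution on the true
#'   edge; `Inf` puts all mass there.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, depth = 2L, branching = 3L,
                           n_per_clade = 4L, aln_length = 120L,
                           divergence = 0.1, gap_fraction = 0.05,
                           diverse_clades = NULL, diverse_rate = 0.5,
                           n_samples = 3L, reads_per_sample = 50L,
                           dup_rate = 0.5, noise_radius = 1L,
                           lwr_alpha = 10) {
  structure(
    list(
      seed = as.integer(seed), depth = as.integer(depth),
      branching = as.integer(branching), n_per_clade = as.integer(n_per_clade),
      aln_length = as.integer(aln_length), divergence = divergence,
      gap_fraction = gap_fraction, diverse_clades = diverse_clades,
      diverse_rate = diverse_rate, n_samples = as.integer(n_samples),
      reads_per_sample = as.integer(reads_per_sample), dup_rate = dup_rate,
      noise_radius = as.integer(noise_radius), lwr_alpha = lwr_alpha
    ),
    class = "fixture_config"
  )
}

# Mutate a character vector sequence: each site is substituted with
# probability `rate` by one of the other three nucleotides (gap sites are
# left untouched).
mutate_sequence <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate & chars != "-"
  if (any(hit)) {
    chars[hit] <- vapply(
      chars[hit],
      function(c) sample(setdiff(c("A", "C", "G", "T"), c), 1L),
      character(1)
    )
  }
  chars
}

#' Generate a toy taxonomy with an evolved alignment
#'
#' Builds a complete `branching`-ary taxonomy of the configured depth.
#' Each top-rank clade gets an independent random ancestral sequence;
#' every child clade's ancestral sequence mutates its parent's per site at
#' the subtree's divergence rate, and each deepest-rank clade attaches
#' `n_per_clade` sequences mutated from its own ancestral sequence. Top
#' clades listed in `diverse_clades` use `diverse_rate` throughout their
#' subtree, planting a known diversity (entropy) ordering. A fixed
#' fraction of columns is turned into shared gap columns.
#'
#' @param cfg A `fixture_config`.
#' @return List with `taxonomy` (see [build_taxonomy()]), `alignment`
#'   (character matrix) and `truth` (data frame `seq_id`, `taxopath`).
#' @export
make_taxonomy_and_alignment <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$aln_length
  gap_cols <- sort(sample.int(L, floor(cfg$gap_fraction * L)))
  seq_rows <- list()
  truth <- list()

  descend <- function(path, anc, rate, level) {
    if (level == cfg$depth) {
      for (k in seq_len(cfg$n_per_clade)) {
        id <- sprintf("%s_s%d", gsub(";", ".", taxopath_string(path)), k)
        seq_rows[[id]] <<- mutate_sequence(anc, rate)
        truth[[length(truth) + 1L]] <<- data.frame(
          seq_id = id, taxopath = taxopath_string(path),
          stringsAsFactors = FALSE
        )
      }
      return(invisible())
    }
    for (j in seq_len(cfg$branching)) {
      child <- c(path, sprintf("%s.%d", path[[length(path)]], j))
      descend(child, mutate_sequence(anc, rate), rate, level + 1L)
    }
  }

  for (i in seq_len(cfg$branching)) {
    top <- sprintf("C%d", i)
    rate <- if (!is.null(cfg$diverse_clades) && top %in% cfg$diverse_clades) {
      cfg$diverse_rate
    } else {
      cfg$divergence
    }
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    anc[gap_cols] <- "-"
    descend(top, anc, rate, 0L)
  }

  truth <- do.call(rbind, truth)
  aln <- do.call(rbind, seq_rows)
  rownames(aln) <- names(seq_rows)
  list(
    taxonomy = build_taxonomy(truth),
    alignment = aln,
    truth = truth
  )
}

#' Generate multi-sample read sets with duplicates
#'
#' Draws each sample's reads (with replacement) from a shared pool of
#' distinct random sequences whose size is controlled by `dup_rate`, so
#' duplicates occur both within and across samples.
#'
#' @param cfg A `fixture_config`.
#' @param read_length Length of the generated reads.
#' @return Named list of character vectors of reads, one per sample.
#' @export
make_read_samples <- function(cfg, read_length = 60L) {
  set.seed(cfg$seed + 1L)
  total <- cfg$n_samples * cfg$reads_per_sample
  pool_size <- max(1L, round(total * (1 - cfg$dup_rate)))
  pool <- vapply(
    seq_len(pool_size),
    function(i) paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                      collapse = ""),
    character(1)
  )
  pool <- unique(pool)
  samples <- lapply(seq_len(cfg$n_samples), function(s) {
    sample(pool, cfg$reads_per_sample, replace = TRUE)
  })
  names(samples) <- sprintf("sample%d", seq_len(cfg$n_samples))
  samples
}

#' Generate a mock placement document with planted truth
#'
#' Stands in for an external placement engine: each query receives
#' candidate placements on its true edge and on all edges within
#' `noise_radius` branches of it. LWRs are drawn from gamma variates with
#' concentration `lwr_alpha` on the true edge (shape 1 elsewhere) and
#' normalized; `lwr_alpha = Inf` yields a single placement with LWR 1 on
#' the true edge. Attachment points are uniform on each edge.
#'
#' @param tree An `edge_tree` with branch lengths.
#' @param truth Named integer vector: query name -> true edge number.
#' @param noise_radius Topological noise radius in branches.
#' @param lwr_alpha LWR concentration on the true edge (`Inf` allowed).
#' @param seed Integer seed.
#' @param multiplicity Multiplicity given to every query.
#' @return A validated `placement_doc`.
#' @export
make_mock_jplace <- function(tree, truth, noise_radius = 0L, lwr_alpha = Inf,
                             seed = 1L, multiplicity = 1) {
  set.seed(seed)
  nums <- edge_numbers(tree)
  unknown <- setdiff(truth, nums)
  if (length(unknown) > 0L) {
    validation_error(sprintf("truth references unknown edge %d", unknown[[1]]))
  }
  pqueries <- lapply(names(truth), function(nm) {
    true_edge <- truth[[nm]]
    if (noise_radius > 0L) {
      d <- edge_topo_distances(tree, true_edge)
      cand <- as.integer(names(d)[!is.na(d) & d <= noise_radius])
      cand <- c(true_edge, setdiff(cand, true_edge))
    } else {
      cand <- true_edge
    }
    if (is.infinite(lwr_alpha)) {
      cand <- true_edge
      lwr <- 1
    } else {
      raw <- rgamma(length(cand), shape = c(lwr_alpha, rep(1, length(cand) - 1L)))
      lwr <- raw / sum(raw)
    }
    lens <- vapply(cand, function(e) edge_info(tree, e)$length, numeric(1))
    list(
      names = data.frame(name = nm, multiplicity = multiplicity,
                         stringsAsFactors = FALSE),
      placements = data.frame(
        edge_num = cand,
        likelihood = -1000 + log(pmax(lwr, 1e-12)),
        like_weight_ratio = lwr,
        distal_length = runif(length(cand)) * lens,
        pendant_length = 0.01
      )
    )
  })
  placement_document(tree, pqueries)
}
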