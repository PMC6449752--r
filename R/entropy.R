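# Per-site entropy, per-set entropy and consensus sequences.
#
# The Shannon entropy of an alignment site i over the five character
# states c in {A, C, G, T, -} is
#
#     H_i = - sum_c f_{c,i} * log2 f_{c,i},
#
# where f_{c,i} is the frequency of state c at site i and 0*log2(0) = 0.
# Counting the gap as a fifth state down-weights gap-rich sites, matching
# how phylogenetic likelihood models treat gaps as uninformative. H_i is 0
# for single-state sites and maximal (log2 5 bits) when all five states
# are equally frequent. The entropy of a sequence set is the sum of its
# per-site entropies and quantifies the ensemble diversity of the set.

#' Per-site character frequencies of an alignment
#'
#' @param aln Alignment matrix (see [read_alignment()]).
#' @return A 5 x L numeric matrix of frequencies, rows named
#'   `A, C, G, T, -`; each column sums to 1.
#' @export
site_frequencies <- function(aln) {
  if (!is.matrix(aln) || nrow(aln) == 0L) value_error("empty sequence set")
  counts <- vapply(
    STATES,
    function(s) colSums(aln == s),
    numeric(ncol(aln))
  )
  # vapply returns L x 5 (or a vector for L = 1); normalize orientation.
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  freqs <- t(counts) / nrow(aln)
  rownames(freqs) <- STATES
  freqs
}

#' Shannon entropy of one site
#'
#' @param freqs Numeric vector of state frequencies (any length; typically
#'   the 5 states `A, C, G, T, -`). Must be non-negative and sum to 1
#'   (tolerance `1e-9`).
#' @return Entropy in bits, in `[0, log2(length(freqs))]`.
#' @examples
#' site_entropy(c(1, 0, 0, 0, 0))      # 0
#' site_entropy(rep(0.2, 5))           # log2(5) = 2.3219...
#' @export
site_entropy <- function(freqs) {
  if (any(freqs < 0)) value_error("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) {
    value_error(sprintf("frequencies sum to %.12f, not 1", sum(freqs)))
  }
  nz <- freqs[freqs > 0]
  -sum(nz * log2(nz)) + 0  # "+ 0" normalizes IEEE negative zero
}

#' Entropy profile of a sequence set
#'
#' Computes the per-site entropies of an alignment (over the five states
#' including the gap), their sum, and the sum normalized by the maximum
#' attainable total `L * log2(5)` so that it lies in `[0, 1]`. The
#' normalized value is for reporting only; all selection decisions use the
#' total.
#'
#' @param seqs Alignment matrix (see [read_alignment()]).
#' @return An object of class `entropy_profile`: list with `per_site`
#'   (numeric vector), `total` and `normalized`.
#' @export
set_entropy <- function(seqs) {
  freqs <- site_frequencies(seqs)
  per_site <- apply(freqs, 2L, site_entropy)
  total <- sum(per_site)
  structure(
    list(
      per_site = per_site,
      total = total,
      normalized = total / (ncol(seqs) * log2(5))
    ),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf(
    "<entropy_profile: %d sites, total %.4f bits, normalized %.4f>\n",
    length(x$per_site), x$total, x$normalized
  ))
  invisible(x)
}

#' Total entropy of the sequences belonging to a clade
#'
#' `set_entropy()` of [clade_sequences()]. A clade whose subtree holds no
#' sequences has entropy 0 by definition (it can never be worth
#' expanding); a warning is emitted in that case.
#'
#' @param tax A `taxonomy`.
#' @param clade Clade id or taxopath.
#' @param alignment Alignment matrix holding all attached sequences.
#' @param cache Optional environment used to memoize per-clade entropies
#'   (a clade's entropy never changes, so repeated queries are free).
#' @return Total entropy in bits.
#' @export
clade_entropy <- function(tax, clade, alignment, cache = NULL) {
  id <- if (is.numeric(clade)) as.integer(clade) else clade_id(tax, clade)
  if (!is.null(cache)) {
    key <- as.character(id)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  seqs <- clade_sequences(tax, id, alignment)
  h <- if (nrow(seqs) == 0L) {
    warning(sprintf("clade '%s' has no sequences; entropy defined as 0", tax$path[[id]]))
    0
  } else {
    set_entropy(seqs)$total
  }
  if (!is.null(cache)) cache[[as.character(id)]] <- h
  h
}

#' Consensus sequence of a sequence set
#'
#' Summarizes an alignment into one sequence, per site:
#'
#' * `majority` — the most frequent of the five states `{A, C, G, T, -}`
#'   (plurality; no quorum required).
#' * `cavener` — the most frequent state if its frequency exceeds 0.5,
#'   otherwise `-`. This collapses Cavener's (1987) consensus rule onto
#'   the five-state alphabet: the two-state ambiguity case (top two states
#'   jointly above 0.75, each above 0.25) has no single-character
#'   representation here and therefore yields a gap.
#' * `threshold` — the most frequent state if its frequency is at least
#'   `threshold`, otherwise `-`.
#'
#' Frequency ties are broken deterministically: non-gap beats gap, then
#' alphabetical order `A < C < G < T`.
#'
#' @param seqs Alignment matrix (see [read_alignment()]).
#' @param method One of `"majority"`, `"cavener"`, `"threshold"`.
#' @param threshold Minimum frequency for the `threshold` method.
#' @return A single sequence string of the alignment's length.
#' @examples
#' aln <- alignment_matrix(c(a = "AAAC", b = "AACC", c = "ATCC"))
#' consensus(aln)                         # majority
#' consensus(aln, "threshold", 0.9)
#' @export
consensus <- function(seqs, method = c("majority", "cavener", "threshold"),
                      threshold = 0.5) {
  method <- match.arg(method)
  freqs <- site_frequencies(seqs)
  # which.max scans rows in STATES order, so ties resolve to non-gap
  # first, then alphabetically.
  top <- apply(freqs, 2L, which.max)
  top_freq <- freqs[cbind(top, seq_len(ncol(freqs)))]
  chars <- STATES[top]
  keep <- switch(method,
    majority = rep(TRUE, length(chars)),
    cavener = top_freq > 0.5,
    threshold = top_freq >= threshold
  )
  chars[!keep] <- "-"
  paste(chars, collapse = "")
}
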