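#' Read a multiple sequence alignment from FASTA
#'
#' Reads an aligned FASTA file into a character matrix (one row per
#' sequence, one column per alignment site). With `normalize = TRUE`
#' (the default) sequences are uppercased, `U` is mapped to `T`, and every
#' character outside `{A, C, G, T, -}` — ambiguity codes, `N`, `.`, etc. —
#' is mapped to the gap character `-`. Gaps take part in all downstream
#' frequency computations as a fifth character state, which down-weights
#' gap-rich sites; ambiguity codes are rare enough in rRNA databases that
#' treating them as gaps has negligible effect.
#'
#' @param path Path to a FASTA file.
#' @param normalize Apply the normalization rules above. Normalization is
#'   idempotent.
#' @return A character matrix with `rownames` set to the sequence
#'   identifiers (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgu", ">s2", "ANR-"), fa)
#' read_alignment(fa)
#' @export
read_alignment <- function(path, normalize = TRUE) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) format_error(paste0("cannot read FASTA: ", conditionMessage(e)))
  )
  if (length(set) == 0L) format_error("empty FASTA file")
  seqs <- as.character(set)
  names(seqs) <- vapply(
    strsplit(names(set), "[[:space:]]+"),
    `[[`, character(1), 1L
  )
  alignment_matrix(seqs, normalize = normalize)
}

#' Build an alignment matrix from named sequence strings
#'
#' @param seqs Named character vector of equal-length sequence strings.
#' @param normalize See [read_alignment()].
#' @return Character matrix, rows = sequences, columns = sites.
#' @export
alignment_matrix <- function(seqs, normalize = TRUE) {
  if (length(seqs) == 0L) format_error("no sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    format_error(sprintf(
      "sequences have unequal lengths (%s): not an alignment",
      paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  if (normalize) seqs <- normalize_sequences(seqs)
  mat <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE,
    dimnames = list(names(seqs), NULL)
  )
  mat
}

#' Normalize nucleotide sequence strings
#'
#' Uppercases, maps `U` to `T` and everything outside `{A, C, G, T, -}`
#' to `-`.
#'
#' @param seqs Character vector of sequence strings.
#' @return Character vector of the same length.
#' @export
normalize_sequences <- function(seqs) {
  up <- toupper(seqs)
  up <- chartr("U", "T", up)
  gsub("[^ACGT-]", "-", up)
}

#' Write an alignment matrix (or named sequences) to FASTA
#'
#' @param x Character matrix as returned by [read_alignment()], or a named
#'   character vector of sequence strings.
#' @param path Output file path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.matrix(x)) {
    seqs <- apply(x, 1L, paste, collapse = "")
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    value_error("sequences must be named to write FASTA")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
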