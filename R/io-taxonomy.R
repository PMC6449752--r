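#' Read a taxonomy table
#'
#' Reads a two-column, tab-separated mapping from sequence identifiers to
#' taxonomic paths in the Silva dialect: `sequence_id TAB
#' Rank1;Rank2;...;RankN` with an optional trailing semicolon. Whitespace
#' around components is stripped. Empty path components and duplicated
#' sequence identifiers are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `seq_id` and `taxopath` (the
#'   normalized `";"`-joined path string). Use [as_taxopath()] to split a
#'   path into its ranks.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("S1\tBacteria;Firmicutes;", "S2\tEukaryota"), tf)
#' read_taxonomy(tf)
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty taxonomy file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    format_error(sprintf("taxonomy line %d has no TAB-separated path", bad[[1]]))
  }
  ids <- trimws(vapply(parts, `[[`, character(1), 1L))
  raw <- trimws(vapply(parts, `[[`, character(1), 2L))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    format_error(sprintf("duplicate sequence id in taxonomy: '%s'", dup[[1]]))
  }
  paths <- vapply(raw, function(p) taxopath_string(as_taxopath(p)), character(1))
  data.frame(seq_id = ids, taxopath = unname(paths), stringsAsFactors = FALSE)
}

#' Write a taxonomy table
#'
#' Inverse of [read_taxonomy()].
#'
#' @param assignments Data frame with columns `seq_id` and `taxopath`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(assignments, path) {
  writeLines(paste0(assignments$seq_id, "\t", assignments$taxopath), path)
  invisible(path)
}
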