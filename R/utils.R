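# Internal helpers shared across modules.

# The five character states used throughout: four nucleotides plus the gap.
# Order matters: ties in frequency-based decisions are broken by position in
# this vector, i.e. non-gap before gap, then alphabetical.
STATES <- c("A", "C", "G", "T", "-")

# Label used in clade associations for backbone edges that belong to no
# clade tree.
INNER_LABEL <- "inner"

stop_phatr <- function(msg, class) {
  stop(structure(
    class = c(class, "phatr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) stop_phatr(msg, "phatr_format_error")
validation_error <- function(msg) stop_phatr(msg, "phatr_validation_error")
value_error <- function(msg) stop_phatr(msg, "phatr_value_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Split or validate a taxonomic path
#'
#' A taxopath is an ordered character vector of rank names, highest rank
#' first (e.g. `c("Bacteria", "Firmicutes")`). Strings are split on `";"`;
#' a trailing separator and surrounding whitespace are tolerated. Empty
#' components are invalid.
#'
#' @param x A character vector of rank names, or a single string with
#'   `";"`-separated ranks.
#' @return A character vector of rank names.
#' @export
as_taxopath <- function(x) {
  if (length(x) == 1L && grepl(";", x, fixed = TRUE)) {
    x <- strsplit(x, ";", fixed = TRUE)[[1]]
  }
  x <- trimws(x)
  x <- x[nzchar(x) | seq_along(x) < length(x)]  # allow trailing empty from "A;B;"
  if (length(x) == 0L || any(!nzchar(x))) {
    format_error("taxopath has an empty component")
  }
  as.character(x)
}

taxopath_string <- function(ranks) paste(ranks, collapse = ";")

# Longest common prefix (as rank vector) of a list of taxopaths.
taxopath_lcp <- function(paths) {
  if (length(paths) == 0L) return(character())
  n <- min(lengths(paths))
  if (n == 0L) return(character())
  out <- character()
  for (i in seq_len(n)) {
    ri <- vapply(paths, `[[`, character(1), i)
    if (all(ri == ri[[1]])) out <- c(out, ri[[1]]) else break
  }
  out
}

# TRUE if `prefix` (rank vector) is a prefix of `path` (rank vector).
taxopath_has_prefix <- function(path, prefix) {
  length(prefix) <= length(path) &&
    all(path[seq_along(prefix)] == prefix)
}

#' Sanitize a taxopath into a newick-safe tip label
#'
#' Ranks are joined with `"."`; characters that are unsafe inside newick
#' strings (whitespace, parentheses, commas, colons, semicolons, quotes and
#' brackets) are replaced by `"_"`.
#'
#' @param ranks Character vector of rank names (or `";"`-separated string).
#' @return A single string usable as a tree tip label.
#' @export
sanitize_label <- function(ranks) {
  s <- paste(as_taxopath(ranks), collapse = ".")
  gsub("[][(){},:;'\"[:space:]]+", "_", s)
}
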