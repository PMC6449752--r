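# Preprocessing of raw per-sample reads for placement.
#
# Identical reads are placed identically, so exact duplicates — within and
# across samples — only waste compute. The pipeline de-duplicates reads
# across all samples, assigns a stable identifier to each unique sequence,
# fuses the unique sequences into equally sized chunks (for even load
# balance when chunks are aligned and placed in parallel), and records
# per-sample abundance counts. After the external aligner and placement
# engine have processed the chunks, the per-chunk placement results are
# resolved back into per-sample documents carrying the original
# abundances.

#' De-duplicate reads across samples into chunks with abundance counts
#'
#' Reads are uppercased and compared by exact string identity (no U/T
#' mapping and no ambiguity handling: deduplication operates on the raw
#' reads). Each unique sequence gets a deterministic identifier — a
#' zero-padded running index in order of first occurrence — and the unique
#' sequences are split into chunks of `chunk_size` (all chunks except the
#' last are full). FASTQ qualities are discarded; placement is
#' sequence-only.
#'
#' @param samples Named list. Each element is either a character vector of
#'   read strings or a single path to a FASTA/FASTQ file.
#' @param chunk_size Number of unique sequences per chunk. Chunks should
#'   be large enough that aligning and placing one chunk amortizes startup
#'   cost; 50000 is a practical default at study scale.
#' @param id_prefix Prefix of the generated sequence identifiers.
#' @return An object of class `dedup_result`: list with `chunks` (list of
#'   named character vectors, id -> sequence), `abundance` (data frame
#'   `sample`, `seq_id`, `count`), `sequences` (all unique sequences,
#'   named by id) and `chunk_size`.
#' @export
deduplicate <- function(samples, chunk_size = 50000L, id_prefix = "u") {
  if (length(samples) == 0L) value_error("need at least one sample")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    value_error("samples must be named")
  }
  if (!is_count(chunk_size)) value_error("chunk_size must be a count >= 1")
  reads <- lapply(samples, function(x) {
    r <- if (length(x) == 1L && file.exists(x)) read_reads(x) else as.character(x)
    toupper(r)
  })
  empty <- names(reads)[lengths(reads) == 0L]
  if (length(empty) > 0L) {
    warning(sprintf("empty sample(s): %s", paste(empty, collapse = ", ")))
  }

  all_reads <- unlist(reads, use.names = FALSE)
  if (length(all_reads) == 0L) value_error("no reads in any sample")
  uniq <- unique(all_reads)  # first-occurrence order across samples
  width <- max(1L, nchar(as.character(length(uniq) - 1L)))
  ids <- sprintf("%s%0*d", id_prefix, width, seq_along(uniq) - 1L)
  id_of <- setNames(ids, uniq)

  abundance <- do.call(rbind, lapply(names(reads), function(s) {
    if (length(reads[[s]]) == 0L) return(NULL)
    tab <- table(id_of[reads[[s]]])
    data.frame(sample = s, seq_id = names(tab), count = as.numeric(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  sequences <- setNames(uniq, ids)
  chunk_idx <- split(seq_along(uniq), ceiling(seq_along(uniq) / chunk_size))
  chunks <- lapply(chunk_idx, function(i) sequences[i])
  names(chunks) <- NULL

  structure(
    list(chunks = chunks, abundance = abundance,
         sequences = sequences, chunk_size = as.integer(chunk_size)),
    class = "dedup_result"
  )
}

# Read a FASTA or FASTQ file into a character vector of read strings.
read_reads <- function(path) {
  first <- readChar(path, 1L, useBytes = TRUE)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  as.character(Biostrings::readBStringSet(path, format = fmt))
}

#' Write chunks, abundance table and manifest to a directory
#'
#' Emits `chunk_<k>.fasta` per chunk, `abundance.tsv` (columns `sample`,
#' `seq_id`, `count`) and a versioned `manifest.json` listing the chunk
#' files and sizes.
#'
#' @param dedup A `dedup_result` (see [deduplicate()]).
#' @param dir Output directory (created if needed).
#' @return Character vector of the chunk file paths, invisibly.
#' @export
write_chunks <- function(dedup, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(dedup$chunks), function(k) {
    p <- file.path(dir, sprintf("chunk_%03d.fasta", k))
    write_fasta(dedup$chunks[[k]], p)
    p
  }, character(1))
  write.table(
    dedup$abundance, file.path(dir, "abundance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- list(
    format_version = 1L,
    chunk_size = dedup$chunk_size,
    n_unique = length(dedup$sequences),
    chunks = lapply(seq_along(paths), function(k) {
      list(file = basename(paths[[k]]), n = length(dedup$chunks[[k]]))
    })
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
    file.path(dir, "manifest.json")
  )
  invisible(paths)
}

#' Read an abundance table
#'
#' @param path Path to a TSV with columns `sample`, `seq_id`, `count`.
#' @return Data frame with those columns.
#' @export
read_abundance <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"))
  if (!identical(names(df), c("sample", "seq_id", "count"))) {
    format_error("abundance table must have columns sample, seq_id, count")
  }
  df
}

#' Resolve per-chunk placement results into per-sample documents
#'
#' Combines the placement documents of the processed chunks with the
#' per-sample abundance counts: for every sample, one pquery is emitted
#' per unique sequence occurring in that sample, carrying the sample's
#' count as multiplicity and the placements of that sequence copied
#' verbatim. All chunk documents must share one reference tree; a
#' sequence placed in more than one chunk is an error, and sequences that
#' were never placed (engines may drop queries) are reported as unplaced.
#'
#' @param chunk_results List of `placement_doc`s, one per chunk.
#' @param abundance Abundance data frame (`sample`, `seq_id`, `count`).
#' @return List with `documents` (named list sample -> `placement_doc`)
#'   and `unplaced` (character vector of sequence ids).
#' @export
resolve_placements <- function(chunk_results, abundance) {
  if (length(chunk_results) == 0L) value_error("no chunk results")
  ref <- write_edge_newick(chunk_results[[1]]$tree)
  for (doc in chunk_results[-1]) {
    if (!identical(write_edge_newick(doc$tree), ref)) {
      validation_error("chunk results disagree on the reference tree")
    }
  }
  placements <- list()
  for (doc in chunk_results) {
    for (pq in doc$pqueries) {
      for (nm in pq$names$name) {
        if (!is.null(placements[[nm]])) {
          validation_error(sprintf("sequence '%s' placed in more than one chunk", nm))
        }
        placements[[nm]] <- pq$placements
      }
    }
  }
  unplaced <- setdiff(unique(abundance$seq_id), names(placements))
  tree <- chunk_results[[1]]$tree
  fields <- chunk_results[[1]]$fields
  documents <- lapply(split(abundance, abundance$sample), function(ab) {
    ab <- ab[!(ab$seq_id %in% unplaced), , drop = FALSE]
    pqs <- lapply(seq_len(nrow(ab)), function(i) {
      list(
        names = data.frame(name = ab$seq_id[[i]],
                           multiplicity = ab$count[[i]],
                           stringsAsFactors = FALSE),
        placements = placements[[ab$seq_id[[i]]]]
      )
    })
    placement_document(tree, pqs, fields = fields)
  })
  list(documents = documents, unplaced = unplaced)
}

#' Deduplication gain
#'
#' The speedup that exact deduplication buys is the ratio of total to
#' unique sequences (each unique sequence is aligned and placed once,
#' regardless of its abundance).
#'
#' @param abundance Abundance data frame (`sample`, `seq_id`, `count`).
#' @return Total reads divided by unique sequences.
#' @export
dedup_gain <- function(abundance) {
  if (nrow(abundance) == 0L) value_error("empty abundance map")
  sum(abundance$count) / length(unique(abundance$seq_id))
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(
    "<dedup_result: %d unique sequences in %d chunk(s) (size %d), %d sample(s), gain %.2f>\n",
    length(x$sequences), length(x$chunks), x$chunk_size,
    length(unique(x$abundance$sample)), dedup_gain(x$abundance)
  ))
  invisible(x)
}
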