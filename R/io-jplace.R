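# jplace v3 documents.
#
# A placement document bundles an edge-numbered reference tree with a list
# of pqueries. Each pquery holds one or more named query sequences (with
# abundance multiplicities) and a list of candidate placements, one per
# candidate edge, each carrying a likelihood weight ratio (LWR). Edges are
# identified solely by their edge number; distal_length is measured from
# the edge's child-side node (see R/io-newick.R).

JPLACE_FIELDS <- c(
  "edge_num", "likelihood", "like_weight_ratio",
  "distal_length", "pendant_length"
)

#' Construct a placement document
#'
#' @param tree An `edge_tree` (see [parse_edge_newick()]).
#' @param pqueries A list; each element is a list with `names` (data frame
#'   with columns `name`, `multiplicity`) and `placements` (data frame
#'   whose columns are the jplace fields, at least `edge_num` and
#'   `like_weight_ratio`).
#' @param fields Ordered character vector of placement field names.
#' @param version jplace format version; only 3 is supported.
#' @param metadata Free-form named list.
#' @return An object of class `placement_doc`.
#' @export
placement_document <- function(tree, pqueries, fields = JPLACE_FIELDS,
                               version = 3L, metadata = list()) {
  doc <- structure(
    list(
      tree = tree, pqueries = pqueries, fields = fields,
      version = as.integer(version), metadata = metadata
    ),
    class = "placement_doc"
  )
  validate_placement_document(doc)
}

#' Validate a placement document
#'
#' Checks that the version is 3, that the mandatory fields are present,
#' that every placement's edge exists in the tree, that LWRs lie in
#' `[0, 1]` and sum to at most 1 (tolerance `1e-6`) per pquery, that
#' `distal_length` does not exceed the edge's branch length (same
#' tolerance) and that multiplicities are at least 1.
#'
#' @param doc A `placement_doc`.
#' @return `doc`, invisibly.
#' @export
validate_placement_document <- function(doc) {
  if (doc$version != 3L) {
    format_error(sprintf("unsupported jplace version %s (expected 3)", doc$version))
  }
  if (!all(c("edge_num", "like_weight_ratio") %in% doc$fields)) {
    format_error("jplace fields must contain edge_num and like_weight_ratio")
  }
  nums <- edge_numbers(doc$tree)
  have_len <- !is.null(doc$tree$phylo$edge.length)
  for (pq in doc$pqueries) {
    pl <- pq$placements
    if (nrow(pl) == 0L) validation_error("pquery without placements")
    unknown <- setdiff(pl$edge_num, nums)
    if (length(unknown) > 0L) {
      validation_error(sprintf("placement references unknown edge %d", unknown[[1]]))
    }
    lwr <- pl$like_weight_ratio
    if (any(lwr < 0 | lwr > 1)) {
      validation_error("like_weight_ratio outside [0, 1]")
    }
    if (sum(lwr) > 1 + 1e-6) {
      validation_error(sprintf("like_weight_ratio sum %.8f exceeds 1", sum(lwr)))
    }
    if (have_len && "distal_length" %in% names(pl)) {
      for (i in seq_len(nrow(pl))) {
        len <- edge_info(doc$tree, pl$edge_num[[i]])$length
        if (pl$distal_length[[i]] > len + 1e-6) {
          validation_error(sprintf(
            "distal_length %.6g exceeds branch length %.6g on edge %d",
            pl$distal_length[[i]], len, pl$edge_num[[i]]
          ))
        }
      }
    }
    if (any(pq$names$multiplicity < 1)) {
      validation_error("pquery multiplicity below 1")
    }
  }
  invisible(doc)
}

#' Read a jplace (v3) file
#'
#' Accepts both the `nm` (name + multiplicity) and the bare `n` pquery
#' naming styles; `n` entries get multiplicity 1.
#'
#' @param path Path to a jplace JSON file.
#' @return A `placement_doc`; see [placement_document()].
#' @export
read_jplace <- function(path) {
  j <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) format_error(paste0("cannot parse jplace JSON: ", conditionMessage(e)))
  )
  for (key in c("tree", "placements", "fields", "version")) {
    if (is.null(j[[key]])) format_error(sprintf("jplace document lacks key '%s'", key))
  }
  fields <- vapply(j$fields, as.character, character(1))
  tree <- parse_edge_newick(j$tree)
  validate_edge_tree(tree)
  pqueries <- lapply(j$placements, function(entry) {
    pl <- as.data.frame(
      do.call(rbind, lapply(entry$p, function(row) {
        if (length(row) != length(fields)) {
          format_error("placement row length does not match fields")
        }
        vapply(row, as.numeric, numeric(1))
      }))
    )
    names(pl) <- fields
    pl$edge_num <- as.integer(pl$edge_num)
    if (!is.null(entry$nm)) {
      nm <- data.frame(
        name = vapply(entry$nm, function(x) as.character(x[[1]]), character(1)),
        multiplicity = vapply(entry$nm, function(x) as.numeric(x[[2]]), numeric(1)),
        stringsAsFactors = FALSE
      )
    } else if (!is.null(entry$n)) {
      nm <- data.frame(
        name = vapply(entry$n, as.character, character(1)),
        multiplicity = 1,
        stringsAsFactors = FALSE
      )
    } else {
      format_error("pquery lacks both 'n' and 'nm'")
    }
    list(names = nm, placements = pl)
  })
  placement_document(
    tree = tree, pqueries = pqueries, fields = fields,
    version = as.integer(j$version),
    metadata = if (is.null(j$metadata)) list() else j$metadata
  )
}

#' Write a placement document as jplace (v3)
#'
#' Always writes the `nm` naming style and brace-tagged edge numbers.
#'
#' @param doc A `placement_doc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(doc, path) {
  validate_placement_document(doc)
  placements <- lapply(doc$pqueries, function(pq) {
    pl <- pq$placements[, doc$fields, drop = FALSE]
    list(
      p = lapply(seq_len(nrow(pl)), function(i) as.numeric(pl[i, ])),
      nm = lapply(seq_len(nrow(pq$names)), function(i) {
        list(pq$names$name[[i]], pq$names$multiplicity[[i]])
      })
    )
  })
  out <- list(
    version = 3L,
    tree = write_edge_newick(doc$tree),
    fields = as.list(doc$fields),
    placements = placements,
    metadata = doc$metadata
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @export
print.placement_doc <- function(x, ...) {
  cat(sprintf(
    "<placement_doc: %d pqueries on a %d-tip tree, fields: %s>\n",
    length(x$pqueries), length(x$tree$phylo$tip.label),
    paste(x$fields, collapse = ", ")
  ))
  invisible(x)
}
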