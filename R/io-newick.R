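# Edge-numbered newick trees.
#
# The jplace format annotates every edge of the reference tree with an
# integer in curly braces directly after the branch length, e.g.
# "((A:0.1{0},B:0.2{1}):0.3{2},C:0.4{3}):0{4};". A legacy dialect puts the
# number in square brackets instead; both are accepted on read, braces are
# emitted on write. ape's newick reader cannot carry these per-edge tags,
# so parsing is done here with a small recursive-descent parser that builds
# an ape "phylo" object plus an aligned edge-number vector.
#
# Coordinate conventions used throughout the package:
#   * edges are identified solely by their edge number;
#   * each edge's child-side node is the node farther from the root;
#   * a placement's distal_length is measured from the child-side node;
#   * a number on the root itself (":0{4}" above) denotes the root edge,
#     an edge hanging above the root whose child-side node is the root.

#' Parse an edge-numbered newick string
#'
#' @param text A newick string with optional `{N}` (or legacy `[N]`) edge
#'   number tags after branch lengths.
#' @return An object of class `edge_tree`: a list with elements
#'   `phylo` (the [ape::read.tree()]-style tree), `edge_num` (integer
#'   vector parallel to the rows of `phylo$edge`; `NA` if the tree carries
#'   no edge numbers), and `root_edge_num` (number of the root edge, or
#'   `NA` if absent).
#' @export
parse_edge_newick <- function(text) {
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) format_error("empty newick string")
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L

  read_label <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c("(", ")", ",", ":", ";", "{", "["))) {
      advance()
    }
    substr(s, start, pos - 1L)
  }
  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9eE.+-]", substr(s, pos, pos))) advance()
    num <- substr(s, start, pos - 1L)
    if (!nzchar(num)) format_error(sprintf("expected a number at position %d", start))
    as.numeric(num)
  }
  read_edge_tag <- function() {
    open <- peek()
    if (!(open %in% c("{", "["))) return(NA_integer_)
    close <- if (open == "{") "}" else "]"
    advance()
    start <- pos
    while (pos <= n && substr(s, pos, pos) != close) advance()
    if (pos > n) format_error("unterminated edge number tag")
    tag <- substr(s, start, pos - 1L)
    advance()
    if (!grepl("^[0-9]+$", tag)) format_error(sprintf("invalid edge number '%s'", tag))
    as.integer(tag)
  }
  parse_clade <- function() {
    node <- list(label = "", children = list(), length = NA_real_, edge_num = NA_integer_)
    if (peek() == "(") {
      advance()
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_clade()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        format_error(sprintf("unexpected character '%s' at position %d", peek(), pos))
      }
      node$label <- read_label()
    } else {
      node$label <- read_label()
      if (!nzchar(node$label)) {
        format_error(sprintf("empty tip label at position %d", pos))
      }
    }
    if (peek() == ":") {
      advance()
      node$length <- read_number()
    }
    node$edge_num <- read_edge_tag()
    node
  }

  root <- parse_clade()
  if (peek() != ";") format_error("newick string must end with ';'")
  build_edge_tree(root)
}

# Convert the nested parse into an ape phylo + edge number vector.
build_edge_tree <- function(root) {
  tips <- character()
  count_tips <- function(nd) {
    if (length(nd$children) == 0L) tips[[length(tips) + 1L]] <<- nd$label
    for (ch in nd$children) count_tips(ch)
  }
  count_tips(root)
  n_tip <- length(tips)
  if (anyDuplicated(tips)) {
    format_error(sprintf("duplicate tip label '%s'", tips[duplicated(tips)][[1]]))
  }
  if (n_tip < 1L) format_error("tree has no tips")

  parent_col <- integer()
  child_col <- integer()
  edge_len <- numeric()
  edge_num <- integer()
  node_label <- character()
  tip_i <- 0L
  node_i <- n_tip + 1L   # ape convention: root is n_tip + 1

  assign_ids <- function(nd) {
    if (length(nd$children) == 0L) {
      tip_i <<- tip_i + 1L
      id <- tip_i
    } else {
      id <- node_i
      node_label[[id - n_tip]] <<- nd$label
      node_i <<- node_i + 1L
    }
    for (ch in nd$children) {
      cid <- assign_ids(ch)
      parent_col[[length(parent_col) + 1L]] <<- id
      child_col[[length(child_col) + 1L]] <<- cid
      edge_len[[length(edge_len) + 1L]] <<- ch$length
      edge_num[[length(edge_num) + 1L]] <<- ch$edge_num
    }
    id
  }
  assign_ids(root)

  n_node <- node_i - n_tip - 1L
  phy <- list(
    edge = cbind(parent_col, child_col, deparse.level = 0),
    tip.label = tips,
    Nnode = n_node
  )
  # Single-tip degenerate trees are not representable in phylo; reject.
  if (nrow(phy$edge) == 0L) format_error("tree must have at least one edge")
  if (!all(is.na(edge_len))) phy$edge.length <- ifelse(is.na(edge_len), 0, edge_len)
  node_label <- c(node_label, character(n_node))[seq_len(n_node)]
  node_label[is.na(node_label)] <- ""
  if (any(nzchar(node_label))) phy$node.label <- node_label
  class(phy) <- "phylo"
  if (!is.na(root$length)) phy$root.edge <- root$length

  # Bring edges into ape's canonical cladewise order, carrying the edge
  # numbers along with the permutation.
  key_old <- paste(phy$edge[, 1L], phy$edge[, 2L])
  phy <- ape::reorder.phylo(phy, "cladewise")
  perm <- match(paste(phy$edge[, 1L], phy$edge[, 2L]), key_old)
  edge_num <- edge_num[perm]

  nums <- edge_num
  root_num <- root$edge_num
  all_nums <- c(nums, if (!is.na(root_num)) root_num)
  if (all(is.na(nums))) {
    nums <- rep(NA_integer_, nrow(phy$edge))
  } else if (anyNA(nums)) {
    format_error("some edges carry an edge number and others do not")
  }
  tree <- structure(
    list(phylo = phy, edge_num = nums, root_edge_num = root_num),
    class = "edge_tree"
  )
  if (!all(is.na(all_nums))) validate_edge_tree(tree)
  tree
}

#' Validate the edge numbering of an `edge_tree`
#'
#' Edge numbers must be unique and cover `0..E-1`, where `E` counts every
#' numbered edge including the root edge if present.
#'
#' @param tree An `edge_tree`.
#' @return `tree`, invisibly.
#' @export
validate_edge_tree <- function(tree) {
  nums <- edge_numbers(tree)
  if (anyNA(nums)) format_error("tree has unnumbered edges")
  if (anyDuplicated(nums)) {
    format_error(sprintf("duplicate edge number %d", nums[duplicated(nums)][[1]]))
  }
  if (!setequal(nums, seq_along(nums) - 1L)) {
    format_error(sprintf(
      "edge numbers must cover 0..%d, got: %s",
      length(nums) - 1L, paste(sort(nums), collapse = ",")
    ))
  }
  invisible(tree)
}

#' All edge numbers of a tree
#'
#' @param tree An `edge_tree`.
#' @return Integer vector of edge numbers (including the root edge's, if
#'   numbered).
#' @export
edge_numbers <- function(tree) {
  c(tree$edge_num, if (!is.na(tree$root_edge_num)) tree$root_edge_num)
}

# Resolve an edge number into its incidence information.
# Returns list(row, parent, child, length). For the root edge, row and
# parent are NA and child is the root node.
edge_info <- function(tree, num) {
  phy <- tree$phylo
  if (!is.na(tree$root_edge_num) && num == tree$root_edge_num) {
    return(list(
      row = NA_integer_, parent = NA_integer_,
      child = as.integer(length(phy$tip.label) + 1L),
      length = if (is.null(phy$root.edge)) 0 else phy$root.edge
    ))
  }
  row <- match(num, tree$edge_num)
  if (is.na(row)) validation_error(sprintf("unknown edge number %s", num))
  len <- if (is.null(phy$edge.length)) 0 else phy$edge.length[[row]]
  list(row = row, parent = phy$edge[row, 1L], child = phy$edge[row, 2L], length = len)
}

# Edge numbers of the subtree hanging below edge `num`, including `num`
# itself. For the root edge this is every edge.
subtree_edge_numbers <- function(tree, num) {
  info <- edge_info(tree, num)
  phy <- tree$phylo
  below <- integer()
  frontier <- info$child
  while (length(frontier) > 0L) {
    rows <- which(phy$edge[, 1L] %in% frontier)
    below <- c(below, rows)
    frontier <- phy$edge[rows, 2L]
  }
  c(num, tree$edge_num[below])
}

# Edge number of the terminal edge leading to the given tip label.
terminal_edge_number <- function(tree, tip_label) {
  phy <- tree$phylo
  tip <- match(tip_label, phy$tip.label)
  if (is.na(tip)) validation_error(sprintf("unknown tip label '%s'", tip_label))
  row <- which(phy$edge[, 2L] == tip)
  tree$edge_num[[row]]
}

#' Write an `edge_tree` as an edge-numbered newick string
#'
#' Edge numbers are emitted in curly braces after branch lengths (the
#' jplace dialect), regardless of the dialect they were read from.
#'
#' @param tree An `edge_tree`.
#' @return A newick string.
#' @export
write_edge_newick <- function(tree) {
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt_num <- function(x) sprintf("%.10g", x)

  render <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) {
      phy$tip.label[[node]]
    } else {
      lbl <- if (!is.null(phy$node.label)) phy$node.label[[node - n_tip]] else ""
      paste0("(", paste(vapply(rows, render_edge, character(1)), collapse = ","), ")", lbl)
    }
  }
  render_edge <- function(row) {
    out <- render(phy$edge[row, 2L])
    if (!is.null(phy$edge.length)) out <- paste0(out, ":", fmt_num(phy$edge.length[[row]]))
    if (!is.na(tree$edge_num[[row]])) out <- paste0(out, "{", tree$edge_num[[row]], "}")
    out
  }
  out <- render(n_tip + 1L)
  if (!is.null(phy$root.edge)) out <- paste0(out, ":", fmt_num(phy$root.edge))
  if (!is.na(tree$root_edge_num)) out <- paste0(out, "{", tree$root_edge_num, "}")
  paste0(out, ";")
}

#' Read an edge-numbered newick file
#'
#' @param path Path to a file whose first non-empty line is a newick
#'   string.
#' @return An `edge_tree`; see [parse_edge_newick()].
#' @export
read_edge_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty newick file")
  parse_edge_newick(paste(lines, collapse = ""))
}

#' @export
print.edge_tree <- function(x, ...) {
  cat(sprintf(
    "<edge_tree: %d tips, %d numbered edges%s>\n",
    length(x$phylo$tip.label),
    sum(!is.na(edge_numbers(x))),
    if (!is.na(x$root_edge_num)) " (incl. root edge)" else ""
  ))
  invisible(x)
}
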