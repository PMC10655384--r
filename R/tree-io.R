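#' @importFrom ape read.tree write.tree unroot root drop.tip Ntip Nnode
#' @importFrom stats rexp runif setNames
#' @importFrom utils combn head
NULL

# Trees are ape "phylo" objects. Branch support lives in node.label (numeric
# strings, 0-100 scale, "" where absent); whether the rooted interpretation is
# authoritative is recorded in attr(tree, "rooted").

#' Is a tree treated as rooted?
#'
#' A tree read from newick is considered rooted when its root node has exactly
#' two children; an unrooted tree is stored rooted-at-an-arbitrary-trifurcation
#' and flagged unrooted. [reroot_on_outgroup()] always returns a rooted tree.
#'
#' @param tree a `phylo` object.
#' @return logical scalar.
#' @export
is_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  r <- attr(tree, "rooted")
  if (!is.null(r)) return(isTRUE(r))
  root <- Ntip(tree) + 1L
  sum(tree$edge[, 1] == root) == 2L
}

`rooted_flag<-` <- function(tree, value) {
  attr(tree, "rooted") <- isTRUE(value)
  tree
}

#' Numeric branch support values per internal node
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `tree$Nnode` (order: nodes
#'   `Ntip+1 ... Ntip+Nnode`), `NA` where no support is recorded.
#' @export
support_values <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  s <- suppressWarnings(as.numeric(tree$node.label))
  length(s) <- n
  s
}

#' Set branch support values
#'
#' @param tree a `phylo` object.
#' @param values numeric vector, length `tree$Nnode`, in `[0, 100]` (`NA`
#'   allowed).
#' @return the tree with `node.label` updated.
#' @export
set_support <- function(tree, values) {
  stopifnot(inherits(tree, "phylo"), length(values) == tree$Nnode)
  if (any(!is.na(values) & (values < 0 | values > 100)))
    stop("support values must lie in [0, 100]")
  lab <- ifelse(is.na(values), "", format(values, trim = TRUE, digits = 10,
                                          scientific = FALSE))
  tree$node.label <- lab
  tree
}

# Pre-scan a newick string so malformed input yields a character offset
# instead of whatever ape does with it.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed newick: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed newick: %d unclosed '(' (end of string at character %d)",
                 depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("malformed newick: missing terminating ';' (string length %d)",
                 nchar(text)))
  invisible(TRUE)
}

# RAxML bipartition-style branch comments: "):0.1[90]" -> ")90:0.1".
promote_comment_support <- function(text) {
  gsub("\\):([0-9.eE+-]+)\\[([0-9.]+)\\]", ")\\2:\\1", text)
}

#' Parse a newick string into a tree
#'
#' Internal node labels that are purely numeric are interpreted as branch
#' support. Supports on a 0-1 scale (all values <= 1) are rescaled to 0-100.
#' Optionally, RAxML-style branch comments (`):0.1[90]`) are promoted to
#' support values first.
#'
#' @param text a single newick string.
#' @param support_in_comments if `TRUE`, extract support from `[...]` branch
#'   comments before parsing (mixed RAxML conventions).
#' @return a `phylo` tree with a `rooted` attribute.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,(B:1,C:1)90:1);")
#' support_values(tr)
parse_newick <- function(text, support_in_comments = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  if (support_in_comments) text <- promote_comment_support(text)
  tree <- tryCatch(read.tree(text = text), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick: ape could not parse the string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label)))
    stop("empty leaf label")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length")
  s <- support_values(tree)
  if (any(!is.na(s))) {
    if (all(s[!is.na(s)] <= 1)) s <- s * 100
    if (any(s[!is.na(s)] < 0 | s[!is.na(s)] > 100))
      stop("support values outside [0, 100] after normalization")
    tree <- set_support(tree, s)
  }
  rooted_flag(tree) <- sum(tree$edge[, 1] == Ntip(tree) + 1L) == 2L
  tree
}

#' Serialize a tree to newick
#'
#' Round-trip safe: `parse_newick(write_newick(t))` is isomorphic to `t`
#' (topology, branch lengths to 10 significant digits, supports). Trees
#' without supports are written without internal labels; multifurcations are
#' preserved.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label)) {
    s <- support_values(tree)
    if (all(is.na(s))) tree$node.label <- NULL else tree <- set_support(tree, s)
  }
  write.tree(tree, digits = digits)
}

#' Read/write one-tree-per-line newick files
#'
#' @param path file path.
#' @param ... passed to [parse_newick()].
#' @return `read_tree_file()`: a list of trees; `write_tree_file()`: the path,
#'   invisibly.
#' @export
read_tree_file <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick, ...)
}

#' @rdname read_tree_file
#' @param trees list of trees.
#' @export
write_tree_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}
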