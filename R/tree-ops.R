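# Clade machinery and rooted-tree operations shared by the QC, concordance
# and quartet stages.

#' Construct a clade
#'
#' A clade is a taxon set (subset of some tree's leaf universe) with an
#' optional support value. Clades of size 1, or spanning a full universe,
#' are trivial and carry no grouping information.
#'
#' @param taxa character vector of taxon labels (deduplicated, sorted).
#' @param support optional numeric support in `[0, 100]`.
#' @return an object of class `clade`.
#' @export
clade <- function(taxa, support = NA_real_) {
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) == 0L) stop("a clade must contain at least one taxon")
  if (!is.na(support) && (support < 0 || support > 100))
    stop("support must lie in [0, 100]")
  structure(list(taxa = taxa, support = as.numeric(support)), class = "clade")
}

#' @export
print.clade <- function(x, ...) {
  cat("<clade> {", paste(x$taxa, collapse = ","), "}",
      if (!is.na(x$support)) sprintf(" support=%g", x$support), "\n", sep = "")
  invisible(x)
}

#' Is a clade trivial on a given universe?
#'
#' @param x a `clade`.
#' @param universe character vector of all taxa in scope.
#' @return logical scalar.
#' @export
is_trivial_clade <- function(x, universe) {
  length(x$taxa) <= 1L || setequal(x$taxa, universe)
}

# Descendant tip-label sets per node, computed by our own postorder sweep
# (kept independent of ape::prop.part so tests can use the latter as an
# oracle). Returns a list indexed by node id; tips map to themselves.
descendant_sets <- function(tree) {
  ntip <- Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]
    chl <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chl]])
  }
  sets
}

#' Non-trivial clades of a rooted tree
#'
#' One clade per internal non-root node, carrying that node's support.
#' Clades equal to the full leaf set are excluded as trivial.
#'
#' @param tree a rooted tree (see [is_rooted()]).
#' @param taxon_map optional named character vector mapping tip labels
#'   (e.g. accessions) to taxon names before taking sets.
#' @return list of `clade` objects.
#' @export
clades_of <- function(tree, taxon_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_rooted(tree))
    stop("clades_of() requires a rooted tree; reroot_on_outgroup() first")
  node_clades(tree, taxon_map)
}

# Same enumeration without the rooted-flag contract (used for split-based
# monophyly checks on unrooted trees, where complements are added too).
node_clades <- function(tree, taxon_map = NULL, drop_trivial = TRUE) {
  ntip <- Ntip(tree)
  sets <- descendant_sets(tree)
  supp <- support_values(tree)
  tips <- map_labels(tree$tip.label, taxon_map)
  out <- list()
  for (j in seq_len(tree$Nnode)) {
    node <- ntip + j
    if (node == ntip + 1L) next  # root
    taxa <- unique(map_labels(sets[[node]], taxon_map))
    if (drop_trivial && (length(taxa) <= 1L || length(taxa) == length(unique(tips))))
      next
    out[[length(out) + 1L]] <- clade(taxa, supp[j])
  }
  out
}

map_labels <- function(labels, taxon_map) {
  if (is.null(taxon_map)) return(labels)
  mapped <- taxon_map[labels]
  ifelse(is.na(mapped), labels, unname(mapped))
}

#' Restrict a clade to a taxon subset
#'
#' @param x a `clade`.
#' @param taxa character vector to intersect with.
#' @return the restricted taxon set as a character vector (possibly empty);
#'   support is carried through as an attribute.
#' @export
restrict_clade <- function(x, taxa) {
  out <- intersect(x$taxa, taxa)
  attr(out, "support") <- x$support
  out
}

#' Do two rooted clades conflict?
#'
#' Rooted clades on a common universe are compatible iff nested or disjoint;
#' they conflict iff the intersection and both set differences are non-empty.
#'
#' @param x,y `clade` objects or plain character vectors of taxa.
#' @return logical scalar.
#' @export
clades_conflict <- function(x, y) {
  a <- if (inherits(x, "clade")) x$taxa else as.character(x)
  b <- if (inherits(y, "clade")) y$taxa else as.character(y)
  length(intersect(a, b)) > 0L &&
    length(setdiff(a, b)) > 0L &&
    length(setdiff(b, a)) > 0L
}

#' Maximum tip-to-tip path length of a tree
#'
#' The default depth notion for branch-length outlier screening. A
#' root-to-tip variant is available for rooted trees via `mode`.
#'
#' @param tree a tree with all branch lengths present.
#' @param mode `"tip_to_tip"` (default) or `"root_to_tip"`.
#' @return a single non-negative number.
#' @export
tip_to_tip_depth <- function(tree, mode = c("tip_to_tip", "root_to_tip")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tip_to_tip_depth() requires branch lengths on every edge")
  depths <- node_depths(tree)
  if (mode == "root_to_tip") return(max(depths[seq_len(Ntip(tree))]))
  max(ape::dist.nodes(tree)[seq_len(Ntip(tree)), seq_len(Ntip(tree))])
}

# Root-to-node path lengths, preorder sweep.
node_depths <- function(tree) {
  n <- Ntip(tree) + tree$Nnode
  d <- numeric(n)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in rev(seq_len(nrow(ord$edge))))
    d[ord$edge[k, 2]] <- d[ord$edge[k, 1]] + ord$edge.length[k]
  d
}

not_rootable <- function(msg) {
  structure(class = c("not_rootable", "tree_rooting_error", "error", "condition"),
            list(message = msg, call = NULL))
}
nonmono_outgroup <- function(msg) {
  structure(class = c("nonmonophyletic_outgroup", "tree_rooting_error",
                      "error", "condition"),
            list(message = msg, call = NULL))
}

#' Root a tree on its outgroup taxa
#'
#' Places the root on the edge separating all outgroup taxa present in the
#' tree from all ingroup taxa. With a single outgroup leaf, the root goes on
#' its pendant edge. Trees lacking any outgroup raise a `not_rootable`
#' condition; trees whose present outgroups cannot be separated from the
#' ingroup by one edge raise a `nonmonophyletic_outgroup` condition — such
#' trees are excluded from rooted analyses rather than force-rooted.
#'
#' @param tree a tree (rooted or unrooted representation).
#' @param outgroups character vector of outgroup taxon labels.
#' @return a rooted tree.
#' @export
reroot_on_outgroup <- function(tree, outgroups) {
  stopifnot(inherits(tree, "phylo"))
  present <- intersect(outgroups, tree$tip.label)
  if (length(present) == 0L)
    stop(not_rootable("no outgroup taxon present in tree"))
  if (length(present) == Ntip(tree))
    stop(not_rootable("tree contains only outgroup taxa"))
  utree <- if (Ntip(tree) > 2L) unroot(tree) else tree
  if (length(present) > 1L && !outgroup_separable(utree, present))
    stop(nonmono_outgroup(paste0("outgroup taxa {",
                                 paste(present, collapse = ","),
                                 "} are not separable from the ingroup by one edge")))
  rooted <- root(utree, outgroup = present, resolve.root = TRUE,
                 edgelabel = TRUE)
  rooted_flag(rooted) <- TRUE
  rooted
}

# Is there an edge of the unrooted tree whose split is exactly
# {present outgroups} vs rest?
outgroup_separable <- function(utree, present) {
  sets <- descendant_sets(utree)
  all_tips <- utree$tip.label
  for (node in seq_along(sets)) {
    if (is.null(sets[[node]])) next
    s <- sets[[node]]
    if (setequal(s, present) || setequal(setdiff(all_tips, s), present))
      return(TRUE)
  }
  FALSE
}
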