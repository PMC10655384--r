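# Gene-tree sanitation: branch-length outlier flagging, low-support branch
# collapse, leaf pruning, and outgroup-availability filtering.

#' Thresholds for gene-tree sanitation
#'
#' A branch is an outlier when its length exceeds a class-specific fraction of
#' the total tree depth: 25% for terminal (ingroup pendant) branches, 50% for
#' internal branches, 75% for outgroup branches (pendant edges of outgroup
#' leaves, or edges subtending all-outgroup groups). Branches with support
#' strictly below `collapse_support` are collapsed into polytomies.
#'
#' @param terminal_fraction,internal_fraction,outgroup_fraction fractions of
#'   tree depth in `(0, 1]`.
#' @param collapse_support support cutoff in `[0, 100]`, default 33.
#' @param outgroups character vector of outgroup taxon labels.
#' @return an `outlier_thresholds` list.
#' @export
outlier_thresholds <- function(terminal_fraction = 0.25,
                               internal_fraction = 0.50,
                               outgroup_fraction = 0.75,
                               collapse_support = 33,
                               outgroups = character(0)) {
  fr <- c(terminal_fraction, internal_fraction, outgroup_fraction)
  stopifnot(all(fr > 0), all(fr <= 1),
            collapse_support >= 0, collapse_support <= 100)
  structure(list(terminal_fraction = terminal_fraction,
                 internal_fraction = internal_fraction,
                 outgroup_fraction = outgroup_fraction,
                 collapse_support = collapse_support,
                 outgroups = as.character(outgroups)),
            class = "outlier_thresholds")
}

#' Flag branches of unreasonable length
#'
#' Each branch is classified as `terminal`, `internal` or `outgroup` (the
#' outgroup class takes precedence: pendant edges of outgroup leaves and edges
#' with an all-outgroup side) and flagged iff its length strictly exceeds the
#' class fraction times the tree depth. Flagged trees are reported for manual
#' review, not auto-pruned; see `auto_prune` in [run_pipeline()] stages for
#' the optional removal of leaves on flagged terminal edges.
#'
#' @param tree a tree with branch lengths.
#' @param cfg an [outlier_thresholds()].
#' @param depth_mode passed to [tip_to_tip_depth()].
#' @return data.frame of flagged branches: `node` (child node id), `tip`
#'   (leaf label for pendant edges, else `NA`), `class`, `length`,
#'   `depth_fraction`.
#' @export
detect_branch_outliers <- function(tree, cfg = outlier_thresholds(),
                                   depth_mode = "tip_to_tip") {
  stopifnot(inherits(tree, "phylo"))
  depth <- tip_to_tip_depth(tree, depth_mode)
  if (depth <= 0) stop("degenerate tree: total depth is 0")
  ntip <- Ntip(tree)
  sets <- descendant_sets(tree)
  all_tips <- tree$tip.label
  out <- data.frame(node = integer(0), tip = character(0),
                    class = character(0), length = numeric(0),
                    depth_fraction = numeric(0))
  limits <- c(terminal = cfg$terminal_fraction,
              internal = cfg$internal_fraction,
              outgroup = cfg$outgroup_fraction)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    len <- tree$edge.length[k]
    side <- sets[[child]]
    is_tip <- child <= ntip
    cls <- if (all(side %in% cfg$outgroups) ||
               all(setdiff(all_tips, side) %in% cfg$outgroups)) {
      "outgroup"
    } else if (is_tip) "terminal" else "internal"
    frac <- len / depth
    if (frac > limits[[cls]])
      out <- rbind(out, data.frame(
        node = child,
        tip = if (is_tip) all_tips[child] else NA_character_,
        class = cls, length = len, depth_fraction = frac))
  }
  out
}

#' Collapse poorly supported branches into polytomies
#'
#' Every internal non-root branch whose support is strictly below the cutoff
#' is contracted; the contracted edge's length is discarded. Absent support is
#' treated as 0 (collapsible). Leaves are never removed, the number of
#' internal nodes never increases, and the operation is idempotent.
#'
#' @param tree a tree with support values.
#' @param collapse_support cutoff in `[0, 100]`; an `outlier_thresholds`
#'   object is also accepted.
#' @return the collapsed tree.
#' @export
collapse_low_support <- function(tree, collapse_support = 33) {
  if (inherits(collapse_support, "outlier_thresholds"))
    collapse_support <- collapse_support$collapse_support
  stopifnot(inherits(tree, "phylo"))
  ntip <- Ntip(tree)
  root <- ntip + 1L
  supp <- support_values(tree)
  supp[is.na(supp)] <- 0
  drop_nodes <- (ntip + seq_len(tree$Nnode))[supp < collapse_support]
  drop_nodes <- setdiff(drop_nodes, root)
  contract_internal_nodes(tree, drop_nodes)
}

# Contract the edges above the given internal nodes: their children reattach
# to the nearest surviving ancestor; the contracted edge length is discarded.
contract_internal_nodes <- function(tree, drop_nodes) {
  if (length(drop_nodes) == 0L) return(tree)
  ntip <- Ntip(tree)
  root <- ntip + 1L
  nnode <- tree$Nnode
  stopifnot(all(drop_nodes > ntip), !(root %in% drop_nodes))
  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  surviving_anc <- function(node) {
    p <- parent[node]
    while (p %in% drop_nodes) p <- parent[p]
    p
  }
  keep_internal <- setdiff(root:(ntip + nnode), drop_nodes)
  new_id <- integer(ntip + nnode)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[keep_internal] <- ntip + seq_along(keep_internal)
  kept_children <- setdiff(seq_len(ntip + nnode), c(root, drop_nodes))
  edge <- cbind(new_id[vapply(kept_children, surviving_anc, integer(1))],
                new_id[kept_children])
  out <- list(edge = edge, Nnode = length(keep_internal),
              tip.label = tree$tip.label)
  if (!is.null(tree$edge.length)) out$edge.length <- elen[kept_children]
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[keep_internal - ntip]
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  rooted_flag(out) <- is_rooted(tree) && is_rooted_topology(out)
  out
}

is_rooted_topology <- function(tree) {
  sum(tree$edge[, 1] == Ntip(tree) + 1L) == 2L
}

#' Remove leaves from a tree
#'
#' Listed leaves are dropped and unary internal nodes suppressed, with branch
#' lengths summed through them, so pairwise path lengths among surviving
#' leaves are preserved exactly.
#'
#' @param tree a tree.
#' @param leaves character vector of leaf labels to remove (must be a subset
#'   of the tree's leaves; at least 2 leaves must remain).
#' @return the pruned tree.
#' @export
prune_leaves <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- as.character(leaves)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing) > 0L)
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(leaves) == 0L) return(tree)
  if (Ntip(tree) - length(leaves) < 2L)
    stop("pruning would leave fewer than 2 leaves")
  was_rooted <- is_rooted(tree)
  out <- drop.tip(tree, leaves, collapse.singles = TRUE)
  rooted_flag(out) <- was_rooted && is_rooted_topology(out)
  out
}

#' Root a set of gene trees on outgroups, excluding unrootable ones
#'
#' Each tree containing at least one outgroup taxon and whose present
#' outgroups are separable from the ingroup is returned rooted; the rest are
#' listed with the reason (`no_outgroup` / `nonmonophyletic_outgroup`).
#'
#' @param trees list of trees.
#' @param outgroups character vector of outgroup labels.
#' @return list with `rooted` (list of rooted trees, names kept) and
#'   `excluded` (data.frame: index, name, reason).
#' @export
filter_trees_with_outgroup <- function(trees, outgroups) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nm <- names(trees)
  if (is.null(nm)) nm <- as.character(seq_along(trees))
  rooted <- list()
  excl <- data.frame(index = integer(0), name = character(0),
                     reason = character(0))
  for (i in seq_along(trees)) {
    res <- tryCatch(reroot_on_outgroup(trees[[i]], outgroups),
                    not_rootable = function(e) "no_outgroup",
                    nonmonophyletic_outgroup = function(e)
                      "nonmonophyletic_outgroup")
    if (is.character(res)) {
      excl <- rbind(excl, data.frame(index = i, name = nm[i], reason = res))
    } else {
      rooted[[nm[i]]] <- res
    }
  }
  list(rooted = rooted, excluded = excl)
}
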