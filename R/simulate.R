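# Multispecies-coalescent (MSC) gene-tree simulator and toy alignment
# fixtures. The simulator provides inputs with the statistical structure the
# downstream analyses assume: gene trees discordant with a known species tree
# through incomplete lineage sorting, with configurable taxon dropout and
# branch-support values.

#' Species-tree model for the MSC simulator
#'
#' A rooted, binary species tree with branch lengths in coalescent units
#' (2N generations). Internal branch lengths must be strictly positive. Tips
#' are assumed contemporaneous: node times are root-to-tip depths measured
#' from the tips, so the tree should be ultrametric.
#'
#' @param tree a `phylo` object or a newick string.
#' @return an object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- Ntip(tree)
  if (sum(tree$edge[, 1] == ntip + 1L) != 2L || !ape::is.binary(tree))
    stop("species tree must be rooted and binary")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("species tree needs branch lengths (coalescent units) on every edge")
  internal_edge <- tree$edge[, 2] > ntip
  if (any(tree$edge.length[internal_edge] <= 0))
    stop("internal branch lengths must be strictly positive")
  depths <- node_depths(tree)
  height <- max(depths[seq_len(ntip)]) - depths
  rooted_flag(tree) <- TRUE
  structure(list(tree = tree, heights = height,
                 children = children_list(tree)),
            class = "species_tree_model")
}

children_list <- function(tree) {
  n <- Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (k in seq_len(nrow(tree$edge)))
    ch[[tree$edge[k, 1]]] <- c(ch[[tree$edge[k, 1]]], tree$edge[k, 2])
  ch
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat(sprintf("<species_tree_model> %d taxa, tree height %.3g coalescent units\n",
              Ntip(x$tree), max(x$heights)))
  invisible(x)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Standard MSC: species-tree branches are traversed tips-to-root; within a
#' branch of duration `t` carrying `k` gene lineages, exponential waiting
#' times with rate `k(k-1)/2` are drawn and uniformly chosen lineage pairs
#' merge while time remains; at the root, coalescence continues until one
#' lineage is left. One lineage is sampled per species. Gene-tree branch
#' lengths are in coalescent units, optionally rescaled.
#'
#' Uses R's global RNG; call `set.seed()` (or use [simulate_gene_tree_set()],
#' which seeds itself) for reproducibility.
#'
#' @param model a [species_tree_model()].
#' @param length_scale multiply gene-tree branch lengths by this factor (e.g.
#'   substitutions per coalescent unit) for depth/outlier testing.
#' @return a rooted `phylo` gene tree on the species labels.
#' @export
simulate_msc_gene_tree <- function(model, length_scale = 1) {
  stopifnot(inherits(model, "species_tree_model"))
  phy <- model$tree
  ntip <- Ntip(phy)
  nnode <- phy$Nnode
  root <- ntip + 1L
  # growing gene-node arrays: 1..ntip are sampled lineages (one per species)
  gtime <- numeric(2L * ntip)
  gleft <- integer(2L * ntip)
  gright <- integer(2L * ntip)
  n_gnodes <- ntip
  lineages <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) lineages[[i]] <- i
  coalesce <- function(lins, t0, t1) {
    t <- t0
    while (length(lins) >= 2L) {
      k <- length(lins)
      t <- t + rexp(1L, rate = k * (k - 1L) / 2)
      if (t > t1) break
      pair <- sample.int(k, 2L)
      n_gnodes <<- n_gnodes + 1L
      gtime[n_gnodes] <<- t
      gleft[n_gnodes] <<- lins[pair[1]]
      gright[n_gnodes] <<- lins[pair[2]]
      lins <- c(lins[-pair], n_gnodes)
    }
    lins
  }
  ord <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]
    chl <- ord$edge[k, 2]
    survivors <- coalesce(lineages[[chl]], model$heights[chl],
                          model$heights[par])
    lineages[[par]] <- c(lineages[[par]], survivors)
  }
  final <- coalesce(lineages[[root]], model$heights[root], Inf)
  stopifnot(length(final) == 1L)
  gene_phylo(phy$tip.label, gtime[seq_len(n_gnodes)],
             gleft[seq_len(n_gnodes)], gright[seq_len(n_gnodes)],
             final, length_scale)
}

# Assemble a phylo object from the coalescent event arrays.
gene_phylo <- function(labels, gtime, gleft, gright, root_id, length_scale) {
  ntip <- length(labels)
  n_internal <- length(gtime) - ntip
  new_id <- integer(length(gtime))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  # preorder renumbering of internal nodes starting at the root
  counter <- ntip
  stack <- root_id
  order_internal <- integer(0)
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node <= ntip) next
    counter <- counter + 1L
    new_id[node] <- counter
    stack <- c(stack, gright[node], gleft[node])
  }
  edge <- matrix(0L, nrow = 2L * n_internal, ncol = 2L)
  elen <- numeric(2L * n_internal)
  r <- 0L
  for (node in seq_along(gtime)) {
    if (node <= ntip) next
    for (child in c(gleft[node], gright[node])) {
      r <- r + 1L
      edge[r, ] <- c(new_id[node], new_id[child])
      elen[r] <- (gtime[node] - gtime[child]) * length_scale
    }
  }
  out <- list(edge = edge, edge.length = elen, Nnode = n_internal,
              tip.label = labels)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  rooted_flag(out) <- TRUE
  out
}

#' Simulation configuration for gene-tree sets
#'
#' @param n_trees number of gene trees.
#' @param dropout per-(leaf, gene) probability of removing a leaf, in
#'   `[0, 1)`; the expected surviving leaf count must stay at least 3, and
#'   trees falling below 3 leaves are redrawn.
#' @param support support model: a single value in `[0, 100]` assigned to
#'   every internal branch, or a length-2 range for independent uniform draws.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_trees, dropout = 0, support = 100, seed = 1L) {
  stopifnot(n_trees >= 1, dropout >= 0, dropout < 1,
            length(support) %in% 1:2, all(support >= 0), all(support <= 100))
  structure(list(n_trees = as.integer(n_trees), dropout = dropout,
                 support = support, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a set of MSC gene trees with dropout and support values
#'
#' @param model a [species_tree_model()].
#' @param cfg a [sim_config()].
#' @param length_scale see [simulate_msc_gene_tree()].
#' @return list of `cfg$n_trees` rooted gene trees (named `gene0001`, ...).
#' @export
simulate_gene_tree_set <- function(model, cfg, length_scale = 1) {
  stopifnot(inherits(model, "species_tree_model"), inherits(cfg, "sim_config"))
  ntaxa <- Ntip(model$tree)
  if (ntaxa * (1 - cfg$dropout) < 3)
    stop("dropout too high: expected surviving leaves per tree below 3")
  local_seed(cfg$seed, {
    trees <- vector("list", cfg$n_trees)
    for (i in seq_len(cfg$n_trees)) {
      repeat {
        gt <- simulate_msc_gene_tree(model, length_scale)
        if (cfg$dropout > 0) {
          drop <- gt$tip.label[runif(ntaxa) < cfg$dropout]
          if (ntaxa - length(drop) < 3L) next
          if (length(drop) > 0L) gt <- prune_leaves(gt, drop)
        }
        break
      }
      supp <- if (length(cfg$support) == 1L) rep(cfg$support, gt$Nnode)
              else runif(gt$Nnode, cfg$support[1], cfg$support[2])
      trees[[i]] <- set_support(gt, supp)
    }
    names(trees) <- sprintf("gene%04d", seq_len(cfg$n_trees))
    trees
  })
}

#' Expected quartet-topology frequencies under the MSC
#'
#' For a quartet separated by an internal branch of `t` coalescent units, the
#' species topology has probability `1 - (2/3) exp(-t)` and each alternative
#' `(1/3) exp(-t)`. Serves as the closed-form oracle for the simulator.
#'
#' @param t internal branch length in coalescent units, `>= 0`.
#' @return named numeric `(f1, f2, f3)`, summing to 1.
#' @export
expected_quartet_freqs <- function(t) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(length(t) == 1L)
  f1 <- 1 - (2 / 3) * exp(-t)
  c(f1 = f1, f2 = (1 - f1) / 2, f3 = (1 - f1) / 2)
}

#' Caterpillar species tree for anomaly-zone experiments
#'
#' Rooted caterpillar `(((A,B),C),D)` with the tipward internal branch set to
#' `x` and the rootward one to `y` coalescent units (pendant branches chosen
#' to keep the tree ultrametric). Short `x`, `y` put the tree in the anomaly
#' zone, where the most probable gene-tree topology differs from the species
#' topology.
#'
#' @param x,y internal branch lengths, `> 0`.
#' @return a [species_tree_model()].
#' @export
make_anomaly_scenario <- function(x, y) {
  stopifnot(x > 0, y > 0)
  nwk <- sprintf("(((A:1,B:1):%.10g,C:%.10g):%.10g,D:%.10g);",
                 x, 1 + x, y, 1 + x + y)
  species_tree_model(nwk)
}

#' Canonical signature of a tree's (rooted) topology
#'
#' Sorted, comma/semicolon-joined clade taxon sets; equal signatures iff the
#' rooted topologies are identical (up to branch lengths and supports).
#'
#' @param tree a tree.
#' @return a character scalar.
#' @export
topology_signature <- function(tree) {
  sets <- descendant_sets(tree)
  ntip <- Ntip(tree)
  keys <- vapply((ntip + 1L):(ntip + tree$Nnode), function(node)
    paste(sort(sets[[node]]), collapse = ","), character(1))
  paste(sort(keys), collapse = ";")
}
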