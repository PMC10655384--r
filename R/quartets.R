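# DiscoVista-style relative quartet-topology frequencies around focal
# branches, and per-group (genus) monophyly classification across gene trees.

#' Define a focal quartet of taxon groups
#'
#' Four named, pairwise disjoint, non-empty taxon groups around a focal
#' species-tree branch. The species-tree resolution is labeled
#' `T1 = G1G2 | G3G4`; the alternatives are `T2 = G1G3 | G2G4` and
#' `T3 = G1G4 | G2G3`.
#'
#' @param g1,g2,g3,g4 character vectors of taxon labels.
#' @return an object of class `clade_quartet`.
#' @export
clade_quartet <- function(g1, g2, g3, g4) {
  groups <- list(G1 = unique(as.character(g1)), G2 = unique(as.character(g2)),
                 G3 = unique(as.character(g3)), G4 = unique(as.character(g4)))
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("all four quartet groups must be non-empty")
  all_taxa <- unlist(groups)
  if (anyDuplicated(all_taxa))
    stop("quartet groups overlap: ",
         paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "))
  structure(groups, class = "clade_quartet")
}

# Topology of the induced unrooted quartet {a,b,c,d} via the four-point
# condition on topological (unit-branch) distances: ab|cd iff
# d(a,b)+d(c,d) < the two other pair sums. Returns 1/2/3 or NA (unresolved).
quartet_topology <- function(dm, a, b, c, d) {
  s <- c(dm[a, b] + dm[c, d], dm[a, c] + dm[b, d], dm[a, d] + dm[b, c])
  lo <- which(s == min(s))
  if (length(lo) != 1L) return(NA_integer_)
  lo
}

topo_dist_matrix <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::dist.nodes(tree)[seq_len(Ntip(tree)), seq_len(Ntip(tree)), drop = FALSE]
}

#' One gene tree's vote among the three quartet resolutions
#'
#' Abstains when any group has no representative in the tree. Otherwise every
#' one-leaf-per-group combination (all of them when at most
#' `max_combinations`, else that many sampled deterministically from `seed`)
#' contributes the topology of its induced unrooted quartet; the tree votes
#' for the majority topology, abstaining on an exact tie. Votes are computed
#' on unrooted induced quartets, so the result is invariant to rerooting.
#'
#' @param gene_tree a tree.
#' @param q a [clade_quartet()].
#' @param max_combinations cap on enumerated representative combinations.
#' @param seed RNG seed used only when sampling combinations beyond the cap.
#' @return integer 1, 2 or 3, or `NA` (abstain).
#' @export
quartet_vote <- function(gene_tree, q, max_combinations = 500, seed = 1L) {
  stopifnot(inherits(q, "clade_quartet"))
  reps <- lapply(q, intersect, y = gene_tree$tip.label)
  if (any(vapply(reps, length, integer(1)) == 0L)) return(NA_integer_)
  sizes <- vapply(reps, length, integer(1))
  dm <- topo_dist_matrix(gene_tree)
  idx <- setNames(seq_len(Ntip(gene_tree)), gene_tree$tip.label)
  n_comb <- prod(sizes)
  if (n_comb <= max_combinations) {
    combos <- as.matrix(expand.grid(reps[[1]], reps[[2]], reps[[3]], reps[[4]],
                                    stringsAsFactors = FALSE))
  } else {
    combos <- local_seed(seed, {
      t(replicate(max_combinations,
                  vapply(reps, sample, character(1), size = 1)))
    })
  }
  votes <- integer(3)
  for (r in seq_len(nrow(combos))) {
    topo <- quartet_topology(dm, idx[[combos[r, 1]]], idx[[combos[r, 2]]],
                             idx[[combos[r, 3]]], idx[[combos[r, 4]]])
    if (!is.na(topo)) votes[topo] <- votes[topo] + 1L
  }
  if (sum(votes) == 0L) return(NA_integer_)
  win <- which(votes == max(votes))
  if (length(win) != 1L) return(NA_integer_)
  win
}

# Evaluate expr under a temporary RNG state derived from seed.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                                envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Quartet-topology frequencies across gene trees
#'
#' @param gene_trees list of trees.
#' @param q a [clade_quartet()].
#' @param ... passed to [quartet_vote()].
#' @return object of class `quartet_frequencies`: list with `counts`
#'   (`n1,n2,n3`), `frequencies` (`f1,f2,f3`, summing to 1), `voting_trees`,
#'   `abstaining_trees`.
#' @export
quartet_frequencies <- function(gene_trees, q, ...) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  votes <- vapply(gene_trees, quartet_vote, integer(1), q = q, ...)
  counts <- c(n1 = sum(votes == 1L, na.rm = TRUE),
              n2 = sum(votes == 2L, na.rm = TRUE),
              n3 = sum(votes == 3L, na.rm = TRUE))
  n <- sum(counts)
  if (n == 0L) stop("no gene tree voted for this quartet")
  structure(list(counts = counts,
                 frequencies = setNames(counts / n, c("f1", "f2", "f3")),
                 voting_trees = n,
                 abstaining_trees = sum(is.na(votes))),
            class = "quartet_frequencies")
}

#' @export
print.quartet_frequencies <- function(x, ...) {
  cat(sprintf("<quartet_frequencies> n=%d voting (%d abstain): f1=%.3f f2=%.3f f3=%.3f\n",
              x$voting_trees, x$abstaining_trees,
              x$frequencies[1], x$frequencies[2], x$frequencies[3]))
  invisible(x)
}

#' Dominant topology and hard-polytomy flag
#'
#' The dominant topology is the most frequent one provided its frequency is at
#' least 1/3; the branch is flagged as a (hard) polytomy when all three
#' frequencies lie within `epsilon` of 1/3 ("roughly equal"). Both can hold
#' simultaneously and both are reported.
#'
#' @param freqs a [quartet_frequencies()] result (or a length-3 numeric).
#' @param epsilon half-width of the "roughly equal" band around 1/3.
#' @return list: `polytomy` (logical), `dominant` (1/2/3 or `NA`).
#' @export
flag_polytomy <- function(freqs, epsilon = 0.05) {
  f <- if (inherits(freqs, "quartet_frequencies")) freqs$frequencies
       else as.numeric(freqs)
  stopifnot(length(f) == 3L, abs(sum(f) - 1) < 1e-9)
  dominant <- as.integer(which.max(f))
  if (f[dominant] < 1 / 3) dominant <- NA_integer_
  list(polytomy = all(abs(f - 1 / 3) <= epsilon), dominant = dominant)
}

#' Monophyly category of a taxon group in one gene tree
#'
#' With fewer than 2 group members present the tree has `no_data`. Otherwise,
#' on the taxa present, the group either forms a clade — `strong_support` when
#' that branch's support meets the threshold, else `weak_support` — or it does
#' not, in which case a sufficiently supported branch conflicting with the
#' group gives `strong_reject`, else `weak_reject`. For trees flagged
#' unrooted, both sides of every split are considered.
#'
#' @param gene_tree a tree.
#' @param group character vector of taxa (e.g. the members of a genus).
#' @param strong_threshold support cutoff separating strong from weak
#'   categories (default 75).
#' @return one of `"strong_support"`, `"weak_support"`, `"weak_reject"`,
#'   `"strong_reject"`, `"no_data"`.
#' @export
monophyly_classify <- function(gene_tree, group, strong_threshold = 75) {
  tips <- gene_tree$tip.label
  present <- intersect(group, tips)
  if (length(present) < 2L) return("no_data")
  if (length(setdiff(tips, present)) == 0L) return("weak_support")
  splits <- node_clades(gene_tree, drop_trivial = TRUE)
  if (!is_rooted(gene_tree)) {
    comp <- lapply(splits, function(cl)
      clade(setdiff(tips, cl$taxa), cl$support))
    splits <- c(splits, Filter(function(cl) length(cl$taxa) > 1L, comp))
  }
  match_idx <- which(vapply(splits, function(cl)
    setequal(cl$taxa, present), logical(1)))
  if (length(match_idx) > 0L) {
    sup <- suppressWarnings(max(vapply(splits[match_idx],
                                       function(cl) cl$support,
                                       numeric(1)), na.rm = TRUE))
    if (is.finite(sup) && sup >= strong_threshold) return("strong_support")
    return("weak_support")
  }
  strong <- Filter(function(cl) !is.na(cl$support) &&
                     cl$support >= strong_threshold, splits)
  for (cl in strong)
    if (clades_conflict(cl$taxa, present)) return("strong_reject")
  "weak_reject"
}

#' Monophyly categories for many groups across many gene trees
#'
#' @param gene_trees list of trees.
#' @param groups named list: group name -> character vector of taxa.
#' @param strong_threshold see [monophyly_classify()].
#' @return data.frame: `group`, `tree` (name or index), `category`; exactly
#'   one row per (group, tree).
#' @export
monophyly_matrix <- function(gene_trees, groups, strong_threshold = 75) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  nm <- names(gene_trees)
  if (is.null(nm)) nm <- as.character(seq_along(gene_trees))
  names(gene_trees) <- nm
  out <- expand.grid(group = names(groups), tree = nm,
                     stringsAsFactors = FALSE)
  out$category <- mapply(function(g, t)
    monophyly_classify(gene_trees[[t]], groups[[g]], strong_threshold),
    out$group, out$tree)
  rownames(out) <- NULL
  out
}
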