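# Test-side helpers and independent oracles (kept on different code paths
# from the implementation: ape::prop.part here vs the package's own postorder
# clade sweep).

# random rooted tree on a label subset, with random supports (NA allowed)
random_supported_tree <- function(labels, p_na = 0.2) {
  k <- length(labels)
  tr <- ape::rtree(k, tip.label = labels)
  supp <- sample(0:100, tr$Nnode, replace = TRUE)
  supp[runif(tr$Nnode) < p_na] <- NA
  tr <- set_support(tr, supp)
  attr(tr, "rooted") <- TRUE
  tr
}

# Brute-force concordance classifier: enumerate every gene-tree clade via
# ape::prop.part and test the set relations directly.
oracle_classify <- function(species_taxa, gene_tree, min_support = 50) {
  gtaxa <- gene_tree$tip.label
  R <- intersect(species_taxa, gtaxa)
  if (length(R) < 2L || length(setdiff(gtaxa, R)) < 1L) return("uninformative")
  pp <- ape::prop.part(gene_tree)
  labs <- attr(pp, "labels")
  supp <- suppressWarnings(as.numeric(gene_tree$node.label))
  concordant <- FALSE
  conflict <- FALSE
  for (j in seq_along(pp)) {
    if (j == 1L) next  # root clade
    set <- labs[pp[[j]]]
    if (length(set) <= 1L || length(set) == length(gtaxa)) next
    s <- supp[j]
    if (is.na(s) || s < min_support) next
    if (setequal(set, R)) concordant <- TRUE
    else if (length(intersect(set, R)) > 0L &&
             length(setdiff(set, R)) > 0L &&
             length(setdiff(R, set)) > 0L) conflict <- TRUE
  }
  if (concordant) "concordant" else if (conflict) "conflict" else "uninformative"
}

# species-tree model with a single internal branch of t coalescent units
# controlling the quartet {A,B} vs {C,D}: caterpillar with a negligible
# second internal branch, so the closed-form 1 - (2/3) exp(-t) applies.
quartet_law_model <- function(t) {
  eps <- 1e-9
  species_tree_model(sprintf(
    "(((A:1,B:1):%.10g,C:%.10g):%.10g,D:%.10g);", t, 1 + t, eps, 1 + t + eps))
}

# labelled tip-to-tip path-length matrix
tip_dist <- function(t) {
  n <- ape::Ntip(t)
  d <- ape::dist.nodes(t)[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(t$tip.label, t$tip.label)
  d
}

# are two trees isomorphic as (possibly unrooted) weighted topologies?
trees_equal <- function(a, b, tol = 1e-8) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  s <- sort(a$tip.label)
  isTRUE(all.equal(tip_dist(a)[s, s], tip_dist(b)[s, s], tolerance = tol))
}
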