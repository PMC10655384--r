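# PhyParts-style mapping of rooted gene trees onto a rooted species tree:
# per-node tallies of concordant / top-alternative / other-conflict /
# uninformative gene trees (the "PhyP = x/y" summaries and pie charts).

#' Concordance configuration
#'
#' @param min_support minimum branch support for a gene-tree clade to count as
#'   evidence (concordant or conflicting); clades below it render the gene
#'   tree uninformative for the node. Default 50, matching the usual
#'   "bootstrap < 50% is no information" convention.
#' @param taxon_map optional named character vector mapping gene-tree tip
#'   labels (accessions) many-to-one onto species-tree taxa; default identity.
#' @return a `concordance_config` list.
#' @export
concordance_config <- function(min_support = 50, taxon_map = NULL) {
  stopifnot(min_support >= 0, min_support <= 100)
  structure(list(min_support = min_support, taxon_map = taxon_map),
            class = "concordance_config")
}

#' Classify one gene tree against one species-tree clade
#'
#' Let `R` be the species clade restricted to the gene tree's taxa. The gene
#' tree is *uninformative* when `R` is trivial on the gene tree (fewer than 2
#' members, or no taxon outside it); *concordant* when some gene-tree clade
#' with support `>= min_support` equals `R`; *conflicting* when no such match
#' exists but some sufficiently supported gene-tree clade conflicts with `R`
#' (see [clades_conflict()]); otherwise uninformative (low support or missing
#' data). Among conflicting clades the one with the smallest symmetric
#' difference to `R` is reported (ties: highest support, then lexicographically
#' smallest taxon set).
#'
#' @param species_clade a [clade()] from the species tree.
#' @param gene_tree a rooted gene tree.
#' @param cfg a [concordance_config()].
#' @return list: `status` (`"concordant"`, `"conflict"` or `"uninformative"`)
#'   and, for conflicts, `alternative` (character vector of taxa).
#' @export
classify_gene_tree <- function(species_clade, gene_tree,
                               cfg = concordance_config()) {
  if (!is_rooted(gene_tree))
    stop("classify_gene_tree() requires a rooted gene tree")
  gclades <- clades_of(gene_tree, cfg$taxon_map)
  gtaxa <- unique(map_labels(gene_tree$tip.label, cfg$taxon_map))
  classify_against_clades(species_clade, gclades, gtaxa, cfg$min_support)
}

# Shared with summarize_concordance so gene-tree clades are enumerated once.
classify_against_clades <- function(species_clade, gclades, gtaxa,
                                    min_support) {
  R <- intersect(species_clade$taxa, gtaxa)
  if (length(R) < 2L || length(setdiff(gtaxa, R)) < 1L)
    return(list(status = "uninformative", alternative = NULL))
  eligible <- Filter(function(cl) !is.na(cl$support) &&
                       cl$support >= min_support, gclades)
  for (cl in eligible)
    if (setequal(cl$taxa, R))
      return(list(status = "concordant", alternative = NULL))
  conflicting <- Filter(function(cl) clades_conflict(cl$taxa, R), eligible)
  if (length(conflicting) == 0L)
    return(list(status = "uninformative", alternative = NULL))
  sd <- vapply(conflicting, function(cl)
    length(setdiff(cl$taxa, R)) + length(setdiff(R, cl$taxa)), numeric(1))
  sup <- vapply(conflicting, function(cl) cl$support, numeric(1))
  key <- vapply(conflicting, function(cl)
    paste(cl$taxa, collapse = ","), character(1))
  ord <- order(sd, -sup, key)
  list(status = "conflict", alternative = conflicting[[ord[1]]]$taxa)
}

#' Per-node concordance summary over a set of gene trees
#'
#' For every internal non-root node of the species tree, tallies how many
#' gene trees are concordant with it, conflict with it (split into the modal
#' alternative clade and all other conflicts), or are uninformative. The
#' counts always sum to the number of gene trees.
#'
#' @param species_tree a rooted species tree.
#' @param gene_trees a non-empty list of rooted gene trees.
#' @param cfg a [concordance_config()].
#' @return data.frame of class `node_concordance`: `node` (species-tree node
#'   id), `clade` (taxa, comma-joined), `concordant`, `top_alternative_count`,
#'   `top_alternative` (taxa or `NA`), `other_conflict`, `uninformative`,
#'   `total`.
#' @export
summarize_concordance <- function(species_tree, gene_trees,
                                  cfg = concordance_config()) {
  if (!is_rooted(species_tree))
    stop("summarize_concordance() requires a rooted species tree")
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (length(gene_trees) == 0L) stop("empty gene-tree list")
  ntip <- Ntip(species_tree)
  sets <- descendant_sets(species_tree)
  node_ids <- setdiff((ntip + 1L):(ntip + species_tree$Nnode), ntip + 1L)
  universe <- unique(map_labels(species_tree$tip.label, cfg$taxon_map))
  gclades <- lapply(gene_trees, function(gt) {
    if (!is_rooted(gt)) stop("all gene trees must be rooted")
    clades_of(gt, cfg$taxon_map)
  })
  gtaxa <- lapply(gene_trees, function(gt)
    unique(map_labels(gt$tip.label, cfg$taxon_map)))
  rows <- lapply(node_ids, function(node) {
    taxa <- unique(map_labels(sets[[node]], cfg$taxon_map))
    if (length(taxa) <= 1L || length(taxa) == length(universe)) return(NULL)
    sc <- clade(taxa)
    conc <- 0L; uninf <- 0L
    alt_counts <- list()
    for (i in seq_along(gene_trees)) {
      res <- classify_against_clades(sc, gclades[[i]], gtaxa[[i]],
                                     cfg$min_support)
      if (res$status == "concordant") conc <- conc + 1L
      else if (res$status == "uninformative") uninf <- uninf + 1L
      else {
        k <- paste(sort(res$alternative), collapse = ",")
        alt_counts[[k]] <- (if (is.null(alt_counts[[k]])) 0L
                            else alt_counts[[k]]) + 1L
      }
    }
    n_conf <- sum(unlist(alt_counts))
    if (n_conf > 0L) {
      cnt <- unlist(alt_counts)
      best <- names(cnt)[order(-cnt, names(cnt))][1]
      top_n <- cnt[[best]]
    } else {
      best <- NA_character_; top_n <- 0L
    }
    data.frame(node = node, clade = paste(sort(taxa), collapse = ","),
               concordant = conc, top_alternative_count = top_n,
               top_alternative = best,
               other_conflict = n_conf - top_n, uninformative = uninf,
               total = length(gene_trees))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = integer(0), clade = character(0),
                      concordant = integer(0),
                      top_alternative_count = integer(0),
                      top_alternative = character(0),
                      other_conflict = integer(0),
                      uninformative = integer(0), total = integer(0))
  class(out) <- c("node_concordance", "data.frame")
  out
}

#' Pie-chart fractions for one concordance row
#'
#' @param nc a one-row slice of a [summarize_concordance()] table (or any list
#'   with the four counts and `total > 0`).
#' @return named numeric: `concordant`, `top_alternative`, `other_conflict`,
#'   `uninformative`; sums to 1 within 1e-12.
#' @export
pie_fractions <- function(nc) {
  total <- nc$total[1]
  if (is.na(total) || total <= 0) stop("pie_fractions: total must be > 0")
  counts <- c(concordant = nc$concordant[1],
              top_alternative = nc$top_alternative_count[1],
              other_conflict = nc$other_conflict[1],
              uninformative = nc$uninformative[1])
  counts / total
}

#' Annotate a species tree with concordance counts
#'
#' Writes `concordant/conflicting` (e.g. `143/15`) as internal node labels,
#' the notation used when reporting per-branch gene-tree agreement.
#'
#' @param species_tree the rooted species tree used in
#'   [summarize_concordance()].
#' @param nc the resulting `node_concordance` table.
#' @return the species tree with annotated node labels.
#' @export
annotate_concordance <- function(species_tree, nc) {
  ntip <- Ntip(species_tree)
  lab <- rep("", species_tree$Nnode)
  conflicts <- nc$top_alternative_count + nc$other_conflict
  lab[nc$node - ntip] <- sprintf("%d/%d", nc$concordant, conflicts)
  species_tree$node.label <- lab
  species_tree
}
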