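# Target-recovery accounting and post-assembly sequence/gene filters.
# Sequences are named character vectors (label -> sequence string); lengths
# are always counted on ungapped residues so alignment state cannot change a
# filtering decision.

GAP_CHARS <- c("-", "?")

ungapped_length <- function(seq) {
  nchar(gsub("[-?]", "", seq))
}

#' Filter configuration for recovery-based QC
#'
#' Defaults follow common HybSeq practice: sequences shorter than 25% of the
#' target length are discarded, and genes represented by fewer than 15
#' sequences are dropped entirely.
#'
#' @param min_length_fraction minimum recovered fraction of the target length,
#'   in `(0, 1]`; sequences strictly below it are removed.
#' @param min_sequences_per_gene minimum number of sequences per gene
#'   (`>= 2`); genes strictly below it are dropped.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_length_fraction = 0.25,
                          min_sequences_per_gene = 15) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            min_sequences_per_gene >= 2)
  structure(list(min_length_fraction = min_length_fraction,
                 min_sequences_per_gene = min_sequences_per_gene),
            class = "filter_config")
}

#' Per-sample, per-gene recovery matrix
#'
#' Recovered fraction = ungapped sequence length / target length. A fraction
#' of 0 means the gene is absent for that sample.
#'
#' @param per_gene_sequences named list: gene -> named character vector of
#'   sequences (sample -> sequence).
#' @param target_lengths named numeric: gene -> target length (positive), in
#'   the same unit as the sequences (amino acids for protein targets;
#'   nucleotides accepted as long as units agree).
#' @return a `recovery_matrix`: list with `fractions` (samples x genes numeric
#'   matrix) and `gene_counts` (named integer, genes recovered per sample).
#' @export
build_recovery_matrix <- function(per_gene_sequences, target_lengths) {
  stopifnot(all(target_lengths > 0))
  genes <- names(per_gene_sequences)
  unknown <- setdiff(genes, names(target_lengths))
  if (length(unknown) > 0L)
    stop("gene(s) without a target length: ", paste(unknown, collapse = ", "))
  samples <- sort(unique(unlist(lapply(per_gene_sequences, names))))
  frac <- matrix(0, nrow = length(samples), ncol = length(genes),
                 dimnames = list(samples, genes))
  for (g in genes) {
    seqs <- per_gene_sequences[[g]]
    if (length(seqs) == 0L) next
    frac[names(seqs), g] <- ungapped_length(seqs) / target_lengths[[g]]
  }
  structure(list(fractions = frac,
                 gene_counts = apply(frac > 0, 1, sum)),
            class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  cat(sprintf("<recovery_matrix> %d samples x %d genes; genes/sample %s\n",
              nrow(x$fractions), ncol(x$fractions),
              if (nrow(x$fractions) > 0)
                paste(range(x$gene_counts), collapse = "-") else "NA"))
  invisible(x)
}

#' Remove sequences shorter than a fraction of the target length
#'
#' A sequence is removed iff its ungapped length is strictly below
#' `min_length_fraction * target_length`; a sequence at exactly the threshold
#' is retained.
#'
#' @param gene_sequences named character vector (sample -> sequence) for one
#'   gene.
#' @param target_length positive target length for the gene.
#' @param cfg a [filter_config()].
#' @return list with `retained` and `removed` named character vectors
#'   (disjoint; union equals the input).
#' @export
filter_short_sequences <- function(gene_sequences, target_length,
                                   cfg = filter_config()) {
  stopifnot(target_length > 0)
  len <- ungapped_length(gene_sequences)
  short <- len < cfg$min_length_fraction * target_length
  list(retained = gene_sequences[!short], removed = gene_sequences[short])
}

#' Drop genes with poor sample representation
#'
#' A gene is dropped iff it contains strictly fewer sequences than
#' `min_sequences_per_gene`.
#'
#' @param genes named list: gene -> named character vector of sequences.
#' @param cfg a [filter_config()].
#' @return list with `retained` and `dropped` gene lists.
#' @export
drop_sparse_genes <- function(genes, cfg = filter_config()) {
  n <- vapply(genes, length, integer(1))
  sparse <- n < cfg$min_sequences_per_gene
  list(retained = genes[!sparse], dropped = genes[sparse])
}

#' Merge two aligned reference sequences into a chimeric target
#'
#' Column by column over a pairwise alignment, the first reference's residue
#' is emitted when present, otherwise the second's; columns gapped in both are
#' skipped. The result carries no gap characters. Used to build a single
#' target representing two partially-covered reference species.
#'
#' @param ref_a,ref_b gapped, equal-length aligned sequences (strings).
#' @return an ungapped chimeric sequence string.
#' @export
build_chimeric_target <- function(ref_a, ref_b) {
  a <- strsplit(ref_a, "", fixed = TRUE)[[1]]
  b <- strsplit(ref_b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("aligned references must have equal length (",
         length(a), " vs ", length(b), ")")
  take_a <- !(a %in% GAP_CHARS)
  take_b <- !take_a & !(b %in% GAP_CHARS)
  out <- character(length(a))
  out[take_a] <- a[take_a]
  out[take_b] <- b[take_b]
  paste(out[take_a | take_b], collapse = "")
}
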