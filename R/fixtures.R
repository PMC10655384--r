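# Toy codon-gene fixtures with exactly known (planted) properties, so the
# sequence/alignment filters can be asserted against a manifest rather than
# against re-derived expectations.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed codon per amino acid (first codon alphabetically is irrelevant;
# any deterministic choice works for threading round trips)
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              "*" = "TAA", X = "NNN", "-" = "---")

reverse_translate <- function(protein) {
  vapply(protein, function(p)
    paste(CODON_OF[strsplit(p, "", fixed = TRUE)[[1]]], collapse = ""),
    character(1), USE.NAMES = TRUE)
}

#' Generate toy per-gene protein/CDS fixtures with planted QC violations
#'
#' Each gene gets `samples` sequences of a common target length. The generator
#' plants, and records in a manifest, exactly: `short_per_gene` unaligned
#' sequences truncated to 20% of the target length (below the 25% recovery
#' filter), internal stop codons at rate `stop_rate` per residue, and
#' low-occupancy alignment columns at rate `gap_fraction` per column (gapped
#' in just over half the rows, so occupancy falls strictly below 50%). CDS
#' sequences are deterministic reverse-translations of the (gapped) protein
#' rows, so codon threading applies exactly.
#'
#' @param genes number of genes.
#' @param samples number of samples per gene (`>= 4`).
#' @param gap_fraction per-column probability of planting a low-occupancy
#'   column, in `[0, 1)`.
#' @param stop_rate per-residue probability of planting an internal stop
#'   codon, in `[0, 1)`.
#' @param seed integer RNG seed (fixed seed, identical fixtures).
#' @param short_per_gene planted short sequences per gene.
#' @param target_length protein target length in residues.
#' @return list with `genes` (per gene: `unaligned_protein`, `unaligned_cds`,
#'   `protein_alignment` (unmasked, may contain `*`), `cds` matching the
#'   alignment rows, `target_length`) and `manifest` (data.frame: `gene`,
#'   `n_samples`, `target_length`, `n_short`, `n_stop_residues`,
#'   `n_low_occupancy_columns`).
#' @export
make_toy_gene_fixtures <- function(genes, samples, gap_fraction = 0.1,
                                   stop_rate = 0.02, seed = 1L,
                                   short_per_gene = 1L, target_length = 90L) {
  stopifnot(genes >= 1, samples >= 4, gap_fraction >= 0, gap_fraction < 1,
            stop_rate >= 0, stop_rate < 1, short_per_gene < samples,
            target_length >= 30)
  local_seed(seed, {
    sample_names <- sprintf("S%03d", seq_len(samples))
    gene_names <- sprintf("gene%03d", seq_len(genes))
    out <- list()
    manifest <- NULL
    for (g in gene_names) {
      prot <- matrix(sample(AA20, samples * target_length, replace = TRUE),
                     nrow = samples,
                     dimnames = list(sample_names, NULL))
      # plant internal stops
      internal <- 2:(target_length - 1L)
      stop_mask <- matrix(FALSE, samples, target_length)
      stop_mask[, internal] <- runif(samples * length(internal)) < stop_rate
      prot[stop_mask] <- "*"
      # plant low-occupancy columns: gapped in floor(n/2)+1 rows (< 50% occ.)
      low_cols <- which(runif(target_length) < gap_fraction)
      n_gapped <- floor(samples / 2) + 1L
      for (cc in low_cols) {
        rows <- sample.int(samples, n_gapped)
        prot[rows, cc] <- "-"
      }
      n_stop <- sum(prot == "*")  # count after gap planting (gaps overwrite)
      aln_rows <- setNames(apply(prot, 1, paste, collapse = ""), sample_names)
      protein_alignment <- alignment(aln_rows, "AA")
      cds <- reverse_translate(gsub("-", "", aln_rows))
      cds <- gsub("-", "", cds, fixed = TRUE)
      # unaligned sequences: gaps stripped; planted shorts truncated to 20%
      unaligned <- gsub("-", "", aln_rows, fixed = TRUE)
      short_samples <- sample(sample_names, short_per_gene)
      short_len <- floor(0.2 * target_length)
      unaligned[short_samples] <- substring(unaligned[short_samples], 1L,
                                            short_len)
      unaligned_cds <- reverse_translate(unaligned)
      out[[g]] <- list(unaligned_protein = unaligned,
                       unaligned_cds = unaligned_cds,
                       protein_alignment = protein_alignment,
                       cds = cds,
                       target_length = target_length,
                       short_samples = short_samples)
      manifest <- rbind(manifest, data.frame(
        gene = g, n_samples = samples, target_length = target_length,
        n_short = short_per_gene, n_stop_residues = n_stop,
        n_low_occupancy_columns = length(low_cols)))
    }
    list(genes = out, manifest = manifest)
  })
}
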