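# Protein-level stop masking, protein-guided codon threading of CDS onto
# amino-acid alignments (pal2nal-like), and occupancy-based column trimming.

#' Construct an alignment
#'
#' A light container: named character rows of equal length plus an alphabet
#' tag. Occupancy and trimming treat `-` and `?` as gaps; ambiguity codes
#' (`N`, `X`) count as occupied.
#'
#' @param rows named character vector (label -> gapped sequence).
#' @param alphabet `"AA"` or `"DNA"`.
#' @return an object of class `alignment`.
#' @export
alignment <- function(rows, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(rows), length(rows) > 0L)
  if (is.null(names(rows)) || anyDuplicated(names(rows)) ||
      any(!nzchar(names(rows))))
    stop("alignment rows need unique, non-empty labels")
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows differ in length: ", paste(w, collapse = ", "))
  structure(rows, alphabet = alphabet, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s, %d rows x %d columns\n",
              attr(x, "alphabet"), length(x), alignment_width(x)))
  invisible(x)
}

#' @rdname alignment
#' @param x an `alignment`.
#' @return `alignment_width()`: the column count.
#' @export
alignment_width <- function(x) {
  if (length(x) == 0L) 0L else nchar(x[[1]])
}

# rows -> character matrix (rows x columns)
alignment_matrix <- function(x) {
  do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
}

matrix_to_alignment <- function(m, labels, alphabet) {
  rows <- apply(m, 1, paste, collapse = "")
  if (length(rows) == 0L) rows <- character(0)
  alignment(setNames(rows, labels), alphabet)
}

#' Mask stop codons in a protein sequence
#'
#' Every `*` is replaced by `X`; length is unchanged. Applied before
#' alignment so aligners do not choke on translated stops.
#'
#' @param protein amino-acid sequence(s), possibly containing `*`.
#' @return sequence(s) with stops masked.
#' @export
mask_stop_codons <- function(protein) {
  chartr("*", "X", protein)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Thread CDS onto a protein alignment (codon-aware back-translation)
#'
#' Each amino-acid column becomes one codon column; a protein gap `-` becomes
#' `---`. For each row the ungapped CDS must be exactly 3x the ungapped
#' protein length; a terminal stop codon in the CDS is stripped first when the
#' protein lacks a terminal `*`/`X` (pal2nal-like tolerance). Rows that still
#' mismatch are excluded, with the failure recorded, and the remaining rows
#' proceed.
#'
#' @param protein_alignment an amino-acid [alignment()].
#' @param cds named character vector of ungapped nucleotide CDS, labels
#'   matching the alignment rows.
#' @return a nucleotide `alignment` of width `3 * ncol(protein_alignment)`;
#'   rows that failed are reported in `attr(, "thread_errors")`
#'   (data.frame: sample, cds_length, protein_length, message).
#' @export
thread_codons <- function(protein_alignment, cds) {
  stopifnot(inherits(protein_alignment, "alignment"),
            attr(protein_alignment, "alphabet") == "AA")
  out <- character(0)
  errs <- data.frame(sample = character(0), cds_length = integer(0),
                     protein_length = integer(0), message = character(0))
  for (label in names(protein_alignment)) {
    prot <- protein_alignment[[label]]
    if (!label %in% names(cds)) {
      errs <- rbind(errs, data.frame(sample = label, cds_length = NA_integer_,
                                     protein_length = ungapped_length(prot),
                                     message = "no CDS for sample"))
      next
    }
    nt <- gsub("[-?]", "", toupper(cds[[label]]))
    aa <- strsplit(prot, "", fixed = TRUE)[[1]]
    res <- aa[!(aa %in% GAP_CHARS)]
    if (nchar(nt) == 3L * (length(res) + 1L) &&
        substring(nt, nchar(nt) - 2L) %in% STOP_CODONS &&
        !(length(res) > 0L && res[length(res)] %in% c("*", "X")))
      nt <- substring(nt, 1L, nchar(nt) - 3L)
    if (nchar(nt) != 3L * length(res)) {
      errs <- rbind(errs, data.frame(
        sample = label, cds_length = nchar(nt),
        protein_length = length(res),
        message = sprintf("CDS length %d != 3 x %d residues",
                          nchar(nt), length(res))))
      next
    }
    codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                        seq(3L, nchar(nt), by = 3L))
    row <- character(length(aa))
    row[aa %in% GAP_CHARS] <- "---"
    row[!(aa %in% GAP_CHARS)] <- codons
    out[[label]] <- paste(row, collapse = "")
  }
  if (nrow(errs) > 0L)
    warning("thread_codons: ", nrow(errs), " row(s) excluded: ",
            paste(errs$sample, collapse = ", "))
  if (length(out) == 0L) stop("thread_codons: no row threaded successfully")
  aln <- alignment(out, "DNA")
  attr(aln, "thread_errors") <- errs
  aln
}

#' Remove low-occupancy alignment columns
#'
#' A column is removed iff the fraction of non-gap rows is strictly below
#' `min_fraction`; a column at exactly the threshold is kept. For nucleotide
#' codon alignments, occupancy is evaluated per codon triple and triples are
#' removed atomically so the reading frame is preserved; set
#' `codon_aware = FALSE` to trim per nucleotide column instead.
#'
#' @param aln an [alignment()].
#' @param min_fraction occupancy threshold in `(0, 1]`, default 0.5.
#' @param codon_aware default: `TRUE` for DNA alignments whose width is a
#'   multiple of 3, else `FALSE`.
#' @return list with `alignment` (trimmed) and `kept_columns` (integer vector
#'   mapping new columns to original 1-based coordinates).
#' @export
trim_low_occupancy_columns <- function(aln, min_fraction = 0.5,
                                       codon_aware = NULL) {
  stopifnot(inherits(aln, "alignment"), min_fraction > 0, min_fraction <= 1)
  w <- alignment_width(aln)
  if (is.null(codon_aware))
    codon_aware <- attr(aln, "alphabet") == "DNA" && w %% 3L == 0L
  m <- alignment_matrix(aln)
  occupied <- !(m %in% GAP_CHARS)
  dim(occupied) <- dim(m)
  if (codon_aware) {
    if (w %% 3L != 0L) stop("codon-aware trimming needs width divisible by 3")
    keep <- logical(w)
    for (t in seq_len(w / 3L)) {
      cols <- (3L * (t - 1L) + 1L):(3L * t)
      occ <- mean(apply(occupied[, cols, drop = FALSE], 1, any))
      keep[cols] <- occ >= min_fraction
    }
  } else {
    keep <- colMeans(occupied) >= min_fraction
  }
  kept <- which(keep)
  out <- matrix_to_alignment(m[, kept, drop = FALSE], names(aln),
                             attr(aln, "alphabet"))
  list(alignment = out, kept_columns = kept)
}

#' Read/write alignments as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O keeping the `alignment` container.
#'
#' @param path FASTA file path.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return `read_fasta_alignment()`: an `alignment`; `write_fasta()`: the
#'   path, invisibly. `read_fasta()` returns a plain named character vector
#'   (rows need not be equal length).
#' @export
read_fasta_alignment <- function(path, alphabet = c("AA", "DNA")) {
  alignment(read_fasta(path), match.arg(alphabet))
}

#' @rdname read_fasta_alignment
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta_alignment
#' @param seqs named character vector or `alignment`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
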