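# Concatenation of per-gene alignments into a partitioned supermatrix, with
# the usual matrix statistics (variable sites, gap fraction).

#' Concatenate gene alignments into a supermatrix
#'
#' One row per sample in the given (or derived) order; a sample absent from a
#' gene is filled with `-` across that gene's columns. Columns are ordered by
#' gene (in list order) and a gene x codon-position partition scheme is
#' emitted, with 1-based inclusive column ranges and stride 3 (RAxML
#' convention). Gene widths must be multiples of 3.
#'
#' @param alignments named list of nucleotide [alignment()]s (gene -> codon
#'   alignment).
#' @param samples ordered character vector of the sample universe; default
#'   the sorted union of all row labels.
#' @return list with `alignment` (the supermatrix) and `scheme` (data.frame:
#'   `name`, `gene`, `codon_position`, `start`, `end`, `stride`).
#' @export
concatenate_alignments <- function(alignments, samples = NULL) {
  stopifnot(length(alignments) > 0L, !is.null(names(alignments)))
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    stopifnot(inherits(aln, "alignment"))
    if (anyDuplicated(names(aln)))
      stop("duplicate sample labels in gene ", g)
    if (alignment_width(aln) %% 3L != 0L)
      stop("gene ", g, " width is not a multiple of 3")
  }
  if (is.null(samples))
    samples <- sort(unique(unlist(lapply(alignments, names))))
  extra <- setdiff(unlist(lapply(alignments, names)), samples)
  if (length(extra) > 0L)
    stop("samples outside the given universe: ", paste(extra, collapse = ", "))
  rows <- setNames(rep("", length(samples)), samples)
  scheme <- data.frame(name = character(0), gene = character(0),
                       codon_position = integer(0), start = integer(0),
                       end = integer(0), stride = integer(0))
  offset <- 0L
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    w <- alignment_width(aln)
    fill <- strrep("-", w)
    block <- setNames(rep(fill, length(samples)), samples)
    block[names(aln)] <- as.character(aln)
    rows <- paste0(rows, block)
    names(rows) <- samples
    for (p in 1:3)
      scheme <- rbind(scheme, data.frame(
        name = sprintf("%s_codon%d", g, p), gene = g, codon_position = p,
        start = offset + p, end = offset + w, stride = 3L))
    offset <- offset + w
  }
  list(alignment = alignment(rows, "DNA"), scheme = scheme)
}

#' Slice a supermatrix back into per-gene alignments
#'
#' Inverse of [concatenate_alignments()] given its partition scheme: each
#' gene's column range is extracted (samples absent from the original gene
#' come back as all-gap rows).
#'
#' @param supermatrix the concatenated [alignment()].
#' @param scheme the partition scheme data.frame.
#' @return named list of alignments, one per gene.
#' @export
deconcatenate_alignments <- function(supermatrix, scheme) {
  out <- list()
  for (g in unique(scheme$gene)) {
    rg <- scheme[scheme$gene == g, ]
    out[[g]] <- alignment(setNames(substring(as.character(supermatrix),
                                             min(rg$start), max(rg$end)),
                                   names(supermatrix)), "DNA")
  }
  out
}

#' Alignment matrix statistics
#'
#' A variable site is a column with at least two distinct unambiguous residues
#' after excluding gaps (`-`, `?`) and ambiguity codes (anything outside
#' `ACGT` for DNA, outside the 20 amino acids for AA). Gap fraction is the
#' percentage of `-`/`?` cells.
#'
#' @param aln an [alignment()].
#' @return list of class `matrix_stats`: `samples`, `columns`,
#'   `variable_sites`, `gap_percent`.
#' @export
matrix_stats <- function(aln) {
  stopifnot(inherits(aln, "alignment"), length(aln) > 0L)
  m <- toupper(alignment_matrix(aln))
  unambiguous <- if (attr(aln, "alphabet") == "DNA") c("A", "C", "G", "T")
                 else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  variable <- 0L
  if (ncol(m) > 0L)
    variable <- sum(apply(m, 2, function(col)
      length(unique(col[col %in% unambiguous])) >= 2L))
  gaps <- sum(m %in% GAP_CHARS)
  structure(list(samples = nrow(m), columns = ncol(m),
                 variable_sites = as.integer(variable),
                 gap_percent = 100 * gaps / length(m)),
            class = "matrix_stats")
}

#' @export
print.matrix_stats <- function(x, ...) {
  cat(sprintf("<matrix_stats> %d samples x %d columns; %d variable sites; %.2f%% gaps\n",
              x$samples, x$columns, x$variable_sites, x$gap_percent))
  invisible(x)
}

#' Write a RAxML-style partition file
#'
#' One line per gene x codon position:
#' `DNA, <gene>_codon<p> = <start>-<end>\3`. Output is byte-stable across
#' runs.
#'
#' @param scheme the partition scheme from [concatenate_alignments()].
#' @param path optional file path; when `NULL` the text is only returned.
#' @return the partition text (character vector of lines), invisibly when
#'   written to a file.
#' @export
write_partition_file <- function(scheme, path = NULL) {
  lines <- sprintf("DNA, %s = %d-%d\\%d",
                   scheme$name, scheme$start, scheme$end, scheme$stride)
  if (nrow(scheme) == 0L) lines <- character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
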