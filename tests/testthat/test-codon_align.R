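test_that("alignment container validates rows", {
  expect_error(alignment(c(A = "MKT", B = "MK"), "AA"), "length")
  expect_error(alignment(c("MKT", "MKL"), "AA"), "labels")
  expect_error(alignment(c(A = "MKT", A = "MKL"), "AA"), "labels")
  a <- alignment(c(S1 = "MKT", S2 = "M-T"), "AA")
  expect_equal(alignment_width(a), 3L)
})

test_that("mask_stop_codons replaces every '*' with 'X'", {
  expect_equal(mask_stop_codons("MKT*LL"), "MKTXLL")
  expect_equal(mask_stop_codons("MKTLL"), "MKTLL")
  expect_equal(mask_stop_codons("***"), "XXX")
  expect_equal(nchar(mask_stop_codons("MK*L*")), 5L)
})

test_that("thread_codons maps codons onto the protein alignment", {
  pa <- alignment(c(S1 = "M-K"), "AA")
  th <- thread_codons(pa, c(S1 = "ATGAAA"))
  expect_equal(as.character(th), c(S1 = "ATG---AAA"), ignore_attr = TRUE)
  expect_equal(alignment_width(th), 3L * alignment_width(pa))

  # trailing stop stripped when the protein lacks a terminal */X
  pa2 <- alignment(c(S1 = "MK"), "AA")
  th2 <- thread_codons(pa2, c(S1 = "ATGAAATAA"))
  expect_equal(unname(as.character(th2)[1]), "ATGAAA")

  # mismatched row excluded, others proceed
  pa3 <- alignment(c(good = "M-K", bad = "MLK"), "AA")
  expect_warning(th3 <- thread_codons(pa3, c(good = "ATGAAA", bad = "ATGCTTAA")),
                 "bad")
  expect_equal(names(th3), "good")
  errs <- attr(th3, "thread_errors")
  expect_equal(errs$sample, "bad")
  expect_equal(errs$cds_length, 8L)
  expect_equal(errs$protein_length, 3L)
})

test_that("thread_codons back-translates to the protein row (property)", {
  set.seed(101)
  fx <- make_toy_gene_fixtures(genes = 3, samples = 6, gap_fraction = 0.15,
                               stop_rate = 0.03, seed = 101)
  translate_back <- function(codon_row) {
    nt <- gsub("-", "", codon_row, fixed = TRUE)
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    rev_map <- setNames(names(phyloconcord:::CODON_OF),
                        phyloconcord:::CODON_OF)
    paste(rev_map[codons], collapse = "")
  }
  for (g in names(fx$genes)) {
    gene <- fx$genes[[g]]
    masked <- alignment(mask_stop_codons(unclass(gene$protein_alignment)),
                        "AA")
    th <- thread_codons(masked, gene$cds)
    expect_equal(nrow(attr(th, "thread_errors")), 0L)
    for (s in names(th)) {
      expected <- gsub("-", "", mask_stop_codons(gene$protein_alignment[[s]]),
                       fixed = TRUE)
      expected <- chartr("*", "X", expected)
      got <- translate_back(th[[s]])
      got <- chartr("*", "X", got)  # TAA reverse-maps to '*'
      expect_equal(got, expected)
    }
  }
})

test_that("trim_low_occupancy_columns uses strict < and whole codons", {
  # 4 rows; codon column 1 occupied by 2/4 rows (exactly 50%) -> kept
  aln <- alignment(c(a = "ATG---", b = "ATGAAA", c = "---AAA", d = "------"),
                   "DNA")
  tr <- trim_low_occupancy_columns(aln, 0.5)
  expect_equal(tr$kept_columns, 1:6)

  # codon column at 25% occupancy -> removed atomically
  aln2 <- alignment(c(a = "ATGCCC", b = "---CCC", c = "---CCC", d = "---CCC"),
                    "DNA")
  tr2 <- trim_low_occupancy_columns(aln2, 0.5)
  expect_equal(tr2$kept_columns, 4:6)
  expect_equal(alignment_width(tr2$alignment), 3L)

  # gap-free alignment unchanged, identity index list
  aln3 <- alignment(c(a = "ATGCCC", b = "TTGCCC"), "DNA")
  tr3 <- trim_low_occupancy_columns(aln3)
  expect_equal(tr3$kept_columns, 1:6)
  expect_equal(as.character(tr3$alignment), as.character(aln3),
               ignore_attr = TRUE)

  # N/X count as occupied; '?' counts as gap
  aln4 <- alignment(c(a = "NNN", b = "???", c = "???", d = "???"), "DNA")
  expect_equal(trim_low_occupancy_columns(aln4, 0.5)$kept_columns,
               integer(0))
  aln5 <- alignment(c(a = "NNN", b = "ANA", c = "???", d = "???"), "DNA")
  expect_equal(trim_low_occupancy_columns(aln5, 0.5)$kept_columns, 1:3)

  # per-nucleotide-column mode
  aln6 <- alignment(c(a = "A-G", b = "A-G", c = "A-G", d = "AAG"), "DNA")
  tr6 <- trim_low_occupancy_columns(aln6, 0.5, codon_aware = FALSE)
  expect_equal(tr6$kept_columns, c(1L, 3L))
})

test_that("trimming is idempotent and column counts are consistent (property)", {
  set.seed(77)
  for (i in 1:20) {
    n_rows <- sample(4:10, 1)
    n_cod <- sample(5:20, 1)
    rows <- vapply(seq_len(n_rows), function(j)
      paste(sample(c("ATG", "CCC", "TTT", "---"), n_cod, replace = TRUE,
                   prob = c(.3, .3, .2, .2)), collapse = ""), character(1))
    aln <- alignment(setNames(rows, paste0("s", seq_len(n_rows))), "DNA")
    tr <- trim_low_occupancy_columns(aln, 0.5)
    expect_equal(alignment_width(tr$alignment),
                 alignment_width(aln) - (alignment_width(aln) -
                                           length(tr$kept_columns)))
    tr2 <- trim_low_occupancy_columns(tr$alignment, 0.5)
    expect_equal(length(tr2$kept_columns), alignment_width(tr$alignment))
    expect_equal(as.character(tr2$alignment), as.character(tr$alignment),
                 ignore_attr = TRUE)
  }
})

test_that("FASTA round trip through Biostrings wrappers", {
  tmp <- tempfile(fileext = ".fasta")
  aln <- alignment(c(S1 = "ATG---AAA", S2 = "ATGCTTAAA"), "DNA")
  write_fasta(aln, tmp)
  back <- read_fasta_alignment(tmp, "DNA")
  expect_equal(as.character(back), as.character(aln), ignore_attr = TRUE)
  expect_equal(names(back), names(aln))
  unlink(tmp)
})
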