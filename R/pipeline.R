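# Configuration-driven driver chaining the stages end-to-end:
# seq_qc -> codon threading/trimming -> (externally inferred gene trees in)
# -> gene-tree QC -> outgroup rooting -> concordance + quartets + supermatrix,
# with a consolidated report. Alignment and tree inference are explicit
# external hand-off points (files in, files out); nothing is shelled out.

#' Pipeline run configuration
#'
#' In-memory variant of the driver configuration: data objects plus all stage
#' thresholds (module defaults unless overridden). File-based runs read their
#' inputs with [read_fasta()] / [read_tree_file()] and pass them here.
#'
#' @param genes named list, gene -> list with `unaligned_protein` (named
#'   character), `protein_alignment` ([alignment()]), `cds` (named character),
#'   `target_length`. The layout produced by [make_toy_gene_fixtures()].
#' @param gene_trees optional named list of gene trees (external inference
#'   hand-off). When `NULL` the tree stages are skipped.
#' @param species_tree optional rooted species tree for the concordance stage.
#' @param outgroups character vector of outgroup taxa.
#' @param filter a [filter_config()].
#' @param thresholds an [outlier_thresholds()] (its `outgroups` field is
#'   filled from `outgroups` if empty).
#' @param concordance a [concordance_config()].
#' @param trim_min_fraction occupancy threshold for column trimming.
#' @param out_dir optional directory; when given, per-stage artifacts (TSV
#'   reports, FASTA, newick, partition file) are written under it.
#' @param seed integer seed recorded in the report.
#' @return a `run_config` list.
#' @export
run_config <- function(genes, gene_trees = NULL, species_tree = NULL,
                       outgroups = character(0),
                       filter = filter_config(),
                       thresholds = outlier_thresholds(),
                       concordance = concordance_config(),
                       trim_min_fraction = 0.5,
                       out_dir = NULL, seed = 1L) {
  stopifnot(is.list(genes), length(genes) > 0L)
  if (length(thresholds$outgroups) == 0L) thresholds$outgroups <- outgroups
  structure(list(genes = genes, gene_trees = gene_trees,
                 species_tree = species_tree, outgroups = outgroups,
                 filter = filter, thresholds = thresholds,
                 concordance = concordance,
                 trim_min_fraction = trim_min_fraction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the post-assembly pipeline end-to-end
#'
#' Stages, in published order: sequence-recovery filtering (short sequences,
#' then sparse genes), stop-codon masking, codon threading, occupancy
#' trimming, supermatrix construction; then, when gene trees are supplied,
#' branch-length outlier flagging, low-support collapse, outgroup rooting, and
#' (when a species tree is supplied) per-node concordance. Every filter
#' decision is logged with its rule and threshold; survival counts chain
#' consistently from stage to stage.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_report` list: `counts` (per-stage survival),
#'   `filter_report` (data.frame of removals), `trimmed` (gene ->
#'   codon alignment), `supermatrix`, `scheme`, `stats`, `outliers`,
#'   `rooted_trees`, `excluded_trees`, `concordance`, `log`, `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0)
  report <- data.frame(gene = character(0), sample = character(0),
                       length = integer(0), target_length = integer(0),
                       action = character(0))
  counts <- list()

  # --- seq_qc: short-sequence filter, then sparse-gene filter
  counts$input_sequences <- sum(vapply(cfg$genes, function(g)
    length(g$unaligned_protein), integer(1)))
  retained <- list()
  for (g in names(cfg$genes)) {
    gene <- cfg$genes[[g]]
    fs <- filter_short_sequences(gene$unaligned_protein, gene$target_length,
                                 cfg$filter)
    for (s in names(fs$removed))
      report <- rbind(report, data.frame(
        gene = g, sample = s, length = ungapped_length(fs$removed[[s]]),
        target_length = gene$target_length,
        action = sprintf("removed_short(<%g of target)",
                         cfg$filter$min_length_fraction)))
    retained[[g]] <- fs$retained
  }
  counts$after_short_filter <- sum(vapply(retained, length, integer(1)))
  log <- log_line(log, "seq_qc: %d/%d sequences pass the %g-length filter",
                  counts$after_short_filter, counts$input_sequences,
                  cfg$filter$min_length_fraction)
  ds <- drop_sparse_genes(retained, cfg$filter)
  for (g in names(ds$dropped))
    report <- rbind(report, data.frame(
      gene = g, sample = NA_character_, length = length(ds$dropped[[g]]),
      target_length = NA_integer_,
      action = sprintf("dropped_sparse_gene(<%d sequences)",
                       cfg$filter$min_sequences_per_gene)))
  kept_genes <- names(ds$retained)
  counts$genes_retained <- length(kept_genes)
  log <- log_line(log, "seq_qc: %d/%d genes pass the >=%d-sequence filter",
                  length(kept_genes), length(cfg$genes),
                  cfg$filter$min_sequences_per_gene)

  # --- codon_align: mask stops, thread, trim (alignment rows are restricted
  # to samples that survived the short-sequence filter)
  trimmed <- list()
  kept_columns <- list()
  for (g in kept_genes) {
    gene <- cfg$genes[[g]]
    rows <- unclass(gene$protein_alignment)
    rows <- rows[names(rows) %in% names(ds$retained[[g]])]
    prot <- alignment(mask_stop_codons(rows), "AA")
    codon <- suppressWarnings(thread_codons(prot, gene$cds))
    tr <- trim_low_occupancy_columns(codon, cfg$trim_min_fraction)
    trimmed[[g]] <- tr$alignment
    kept_columns[[g]] <- tr$kept_columns
    log <- log_line(log, "codon_align: %s trimmed %d -> %d columns (occupancy >= %g)",
                    g, alignment_width(codon), alignment_width(tr$alignment),
                    cfg$trim_min_fraction)
  }
  counts$genes_aligned <- length(trimmed)

  # --- supermatrix
  super <- NULL; scheme <- NULL; stats <- NULL
  if (length(trimmed) > 0L &&
      all(vapply(trimmed, alignment_width, integer(1)) > 0L)) {
    cc <- concatenate_alignments(trimmed)
    super <- cc$alignment
    scheme <- cc$scheme
    stats <- matrix_stats(super)
    log <- log_line(log, "supermatrix: %d samples x %d columns, %d variable sites, %.2f%% gaps",
                    stats$samples, stats$columns, stats$variable_sites,
                    stats$gap_percent)
  }

  # --- gene-tree stages
  outliers <- NULL; rooted <- NULL; excluded <- NULL; conc <- NULL
  if (!is.null(cfg$gene_trees)) {
    counts$input_gene_trees <- length(cfg$gene_trees)
    outliers <- do.call(rbind, lapply(names(cfg$gene_trees), function(nm) {
      fl <- detect_branch_outliers(cfg$gene_trees[[nm]], cfg$thresholds)
      if (nrow(fl) > 0L) cbind(tree = nm, fl) else NULL
    }))
    log <- log_line(log, "genetree_qc: %d branch-length outliers flagged (terminal>%g, internal>%g, outgroup>%g of depth)",
                    if (is.null(outliers)) 0L else nrow(outliers),
                    cfg$thresholds$terminal_fraction,
                    cfg$thresholds$internal_fraction,
                    cfg$thresholds$outgroup_fraction)
    collapsed <- lapply(cfg$gene_trees, collapse_low_support,
                        collapse_support = cfg$thresholds$collapse_support)
    log <- log_line(log, "genetree_qc: branches with support < %g collapsed",
                    cfg$thresholds$collapse_support)
    fr <- filter_trees_with_outgroup(collapsed, cfg$outgroups)
    rooted <- fr$rooted
    excluded <- fr$excluded
    counts$rooted_gene_trees <- length(rooted)
    log <- log_line(log, "rooting: %d/%d gene trees rooted on outgroups {%s}",
                    length(rooted), length(collapsed),
                    paste(cfg$outgroups, collapse = ","))
    if (!is.null(cfg$species_tree) && length(rooted) > 0L) {
      conc <- summarize_concordance(cfg$species_tree, rooted,
                                    cfg$concordance)
      log <- log_line(log, "concordance: %d species-tree nodes tallied over %d rooted gene trees (min support %g)",
                      nrow(conc), length(rooted),
                      cfg$concordance$min_support)
    }
  }

  out <- structure(list(counts = counts, filter_report = report,
                        trimmed = trimmed, kept_columns = kept_columns,
                        supermatrix = super, scheme = scheme, stats = stats,
                        outliers = outliers, rooted_trees = rooted,
                        excluded_trees = excluded, concordance = conc,
                        log = log, seed = cfg$seed),
                   class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$filter_report, file.path(out_dir, "filter_report.tsv"))
  for (g in names(report$trimmed))
    write_fasta(report$trimmed[[g]],
                file.path(out_dir, paste0(g, ".trimmed.fasta")))
  if (!is.null(report$supermatrix)) {
    write_fasta(report$supermatrix, file.path(out_dir, "supermatrix.fasta"))
    write_partition_file(report$scheme, file.path(out_dir, "partitions.txt"))
    write_tsv(data.frame(samples = report$stats$samples,
                         columns = report$stats$columns,
                         variable_sites = report$stats$variable_sites,
                         gap_percent = report$stats$gap_percent),
              file.path(out_dir, "matrix_stats.tsv"))
  }
  if (!is.null(report$outliers))
    write_tsv(report$outliers, file.path(out_dir, "branch_outliers.tsv"))
  if (!is.null(report$rooted_trees) && length(report$rooted_trees) > 0L)
    write_tree_file(report$rooted_trees,
                    file.path(out_dir, "rooted_gene_trees.nwk"))
  if (!is.null(report$concordance))
    write_tsv(report$concordance, file.path(out_dir, "concordance.tsv"))
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
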