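test_that("species_tree_model validates its contract", {
  expect_error(species_tree_model("(A,B,(C,D));"), "rooted and binary")
  expect_error(species_tree_model("((A:1,B:1):0,(C:1,D:1):1);"),
               "strictly positive")
  expect_error(species_tree_model("((A,B),(C,D));"), "branch lengths")
  m <- species_tree_model("((A:1,B:1):1,(C:1,D:1):1);")
  expect_s3_class(m, "species_tree_model")
  expect_equal(max(m$heights), 2)
})

node_depths_of <- function(gt) {
  ape::dist.nodes(gt)[ape::Ntip(gt) + 1L, seq_len(ape::Ntip(gt))]
}

test_that("pairwise coalescence time in one population is Exp(1)", {
  # 2-taxon model: lineages meet at the root and coalesce at rate 1, so the
  # gene-tree depth exceeds the species divergence by an Exp(1) draw
  m <- species_tree_model("(A:1,B:1);")
  set.seed(2)
  n <- 10000
  extra <- vapply(seq_len(n), function(i) {
    gt <- simulate_msc_gene_tree(m)
    max(node_depths_of(gt)) - 1
  }, numeric(1))
  se <- 1 / sqrt(n)  # sd of Exp(1) is 1
  expect_lt(abs(mean(extra) - 1), 3 * se)
  expect_true(all(extra > 0))
})

test_that("deep species-tree branches give near-total concordance", {
  # internal branches of 10 coalescent units: match probability
  # 1 - (2/3) exp(-10) > 0.9997
  m <- species_tree_model("((A:1,B:1):10,(C:11,D:11):10);")
  set.seed(3)
  sig <- replicate(500, topology_signature(simulate_msc_gene_tree(m)))
  species_sig <- topology_signature(m$tree)
  expect_gt(mean(sig == species_sig), 0.99)
})

test_that("simulated quartet frequencies match the closed form (property)", {
  q <- clade_quartet("A", "B", "C", "D")
  set.seed(4)
  # scaled down from the 10,000-tree acceptance runs to keep the unit suite
  # fast; the acceptance test runs the full sizes
  n <- 2000
  for (t in c(0.5, 2)) {
    m <- quartet_law_model(t)
    votes <- integer(3)
    for (i in seq_len(n)) {
      v <- quartet_vote(simulate_msc_gene_tree(m), q)
      votes[v] <- votes[v] + 1L
    }
    f <- expected_quartet_freqs(t)
    se <- sqrt(f[1] * (1 - f[1]) / n)
    expect_lt(abs(votes[1] / n - f[1]), 3 * se)
  }
})

test_that("expected_quartet_freqs evaluates the MSC law", {
  expect_equal(unname(expected_quartet_freqs(0)), rep(1 / 3, 3))
  expect_equal(unname(expected_quartet_freqs(1)),
               c(0.75475, 0.12263, 0.12263), tolerance = 5e-5)
  expect_equal(unname(expected_quartet_freqs(50)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(sum(expected_quartet_freqs(0.37)), 1)
  expect_error(expected_quartet_freqs(-1), "non-negative")
})

test_that("topology spectrum agrees with msprime (cross-oracle)", {
  # independent coalescent simulator on the same balanced model, compared by
  # chi-square on the three unrooted quartet topologies
  n <- 2000
  script <- paste(
    "import msprime, collections",
    "dem = msprime.Demography.from_species_tree(",
    "    '((A:1,B:1)AB:1,(C:1,D:1)CD:1)R;', initial_size=1)",
    "counts = [0, 0, 0]",
    sprintf("reps = msprime.sim_ancestry(samples={'A':1,'B':1,'C':1,'D':1}, demography=dem, ploidy=1, num_replicates=%d, random_seed=99)", n),
    "for ts in reps:",
    "    t = ts.first()",
    "    a, b, c, d = 0, 1, 2, 3",
    "    s = [t.tmrca(a,b)+t.tmrca(c,d), t.tmrca(a,c)+t.tmrca(b,d), t.tmrca(a,d)+t.tmrca(b,c)]",
    "    counts[s.index(min(s))] += 1",
    "print(*counts)",
    sep = "\n")
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", py, stdout = TRUE, stderr = FALSE, timeout = 300)
  unlink(py)
  ms_counts <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_length(ms_counts, 3L)

  m <- species_tree_model("((A:1,B:1):1,(C:1,D:1):1);")
  q <- clade_quartet("A", "B", "C", "D")
  set.seed(6)
  votes <- integer(3)
  for (i in seq_len(n)) {
    v <- quartet_vote(simulate_msc_gene_tree(m), q)
    votes[v] <- votes[v] + 1L
  }
  # pool the two (symmetric) minor topologies to stabilize the comparison
  tab <- rbind(ours = c(votes[1], votes[2] + votes[3]),
               msprime = c(ms_counts[1], ms_counts[2] + ms_counts[3]))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("dropout and support models behave as configured", {
  m <- species_tree_model(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:2,F:2):1,(G:2,H:2):1):1);")
  full <- simulate_gene_tree_set(m, sim_config(50, dropout = 0, seed = 12))
  expect_length(full, 50L)
  expect_true(all(vapply(full, ape::Ntip, integer(1)) == 8L))
  expect_true(all(vapply(full, function(t)
    all(support_values(t) == 100), logical(1))))

  dropped <- simulate_gene_tree_set(m,
    sim_config(400, dropout = 0.1, seed = 13))
  n_leaves <- vapply(dropped, ape::Ntip, integer(1))
  expect_true(all(n_leaves >= 3L))
  # binomial expectation: mean leaves ~ 7.2, se ~ sqrt(8*.1*.9/400)
  expect_lt(abs(mean(n_leaves) - 7.2), 3 * sqrt(8 * 0.1 * 0.9 / 400) + 0.05)

  rng <- simulate_gene_tree_set(m,
    sim_config(20, support = c(20, 60), seed = 14))
  sv <- unlist(lapply(rng, support_values))
  expect_true(all(sv >= 20 & sv <= 60))

  expect_error(sim_config(10, dropout = 1), "dropout")
  expect_error(simulate_gene_tree_set(
    species_tree_model("((A:1,B:1):1,(C:1,D:1):1);"),
    sim_config(5, dropout = 0.9)), "dropout too high")
})

test_that("fixed seeds give byte-identical gene-tree sets", {
  m <- species_tree_model("((A:1,B:1):1,(C:1,D:1):1);")
  a <- simulate_gene_tree_set(m, sim_config(10, dropout = 0.2, seed = 7))
  b <- simulate_gene_tree_set(m, sim_config(10, dropout = 0.2, seed = 7))
  expect_identical(vapply(a, write_newick, character(1)),
                   vapply(b, write_newick, character(1)))
  c_ <- simulate_gene_tree_set(m, sim_config(10, dropout = 0.2, seed = 8))
  expect_false(identical(vapply(a, write_newick, character(1)),
                         vapply(c_, write_newick, character(1))))
})

test_that("make_anomaly_scenario builds the caterpillar model", {
  m <- make_anomaly_scenario(0.05, 0.05)
  expect_equal(ape::Ntip(m$tree), 4L)
  expect_true(ape::is.binary(m$tree))
  sig <- topology_signature(m$tree)
  expect_true(grepl("A,B;A,B,C", sig))
  # high-t limit: modal topology IS the species topology
  m5 <- make_anomaly_scenario(5, 5)
  set.seed(21)
  sigs <- replicate(300, topology_signature(simulate_msc_gene_tree(m5)))
  expect_equal(names(sort(table(sigs), decreasing = TRUE))[1],
               topology_signature(m5$tree))
})

test_that("make_toy_gene_fixtures plants exactly what the manifest records", {
  fx <- make_toy_gene_fixtures(genes = 3, samples = 8, gap_fraction = 0.12,
                               stop_rate = 0.03, seed = 5, short_per_gene = 2)
  expect_equal(nrow(fx$manifest), 3L)
  for (g in names(fx$genes)) {
    gene <- fx$genes[[g]]
    man <- fx$manifest[fx$manifest$gene == g, ]
    # planted short sequences are exactly the removed set
    fs <- filter_short_sequences(gene$unaligned_protein, gene$target_length,
                                 filter_config())
    expect_setequal(names(fs$removed), gene$short_samples)
    expect_equal(length(fs$removed), man$n_short)
    # planted stops are exactly the masked residues
    rows <- unclass(gene$protein_alignment)
    n_changed <- sum(mapply(function(orig, masked)
      sum(strsplit(orig, "")[[1]] != strsplit(masked, "")[[1]]),
      rows, mask_stop_codons(rows)))
    expect_equal(n_changed, man$n_stop_residues)
    # planted low-occupancy protein columns are exactly the trimmed triples
    masked <- alignment(mask_stop_codons(rows), "AA")
    codon <- thread_codons(masked, gene$cds)
    tr <- trim_low_occupancy_columns(codon, 0.5)
    removed_cols <- alignment_width(codon) - length(tr$kept_columns)
    expect_equal(removed_cols, 3L * man$n_low_occupancy_columns)
  }
  # determinism
  fx2 <- make_toy_gene_fixtures(genes = 3, samples = 8, gap_fraction = 0.12,
                                stop_rate = 0.03, seed = 5, short_per_gene = 2)
  expect_identical(fx$manifest, fx2$manifest)
  expect_identical(fx$genes$gene001$unaligned_protein,
                   fx2$genes$gene001$unaligned_protein)
})
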