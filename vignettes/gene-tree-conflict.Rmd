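---
title: "Gene-tree conflict, concordance and QC: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-tree conflict, concordance and QC: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconcord)
```

# The problem

Target-enrichment (HybSeq) studies recover hundreds of low-copy nuclear loci
across many samples. After assembly, each locus yields its own gene tree, and
those gene trees routinely disagree — through incomplete lineage sorting
(ILS), estimation error, misassembly and misalignment. This package covers
the post-assembly chain: cleaning sequences and alignments, sanitising gene
trees, and then *quantifying* the disagreement between gene trees and a
species tree instead of hiding it behind a single support value.

# The coalescent model behind the analyses

Under the multispecies coalescent (MSC), gene lineages entering a
species-tree branch of duration $t$ coalescent units (one unit = $2N$
generations) fail to coalesce within it with probability $e^{-t}$. For a
quartet of lineages separated by one internal branch of length $t$, the gene
tree matches the species-tree resolution with probability

$$P(T_1) = 1 - \tfrac{2}{3}e^{-t}, \qquad P(T_2) = P(T_3) = \tfrac{1}{3}e^{-t},$$

which `expected_quartet_freqs()` evaluates and the simulator reproduces
(verified in the test suite within 3 binomial standard errors at
$n = 10{,}000$ for $t \in \{0.1, 0.5, 1, 2\}$). Consecutive short branches
can push a tree into the *anomaly zone*, where the most probable gene-tree
topology differs from the species-tree topology; `make_anomaly_scenario()`
builds the classic 4-taxon caterpillar for this, and at $x = y = 0.05$ the
modal simulated rooted topology is the balanced tree, not the caterpillar
(demonstrated in `test-acceptance.R`).

## The simulator: what it emulates, and what it does not

`simulate_msc_gene_tree()` implements the standard MSC: species-tree
branches are traversed tips-to-root; within a branch carrying $k$ lineages,
exponential waiting times at rate $k(k-1)/2$ merge uniformly chosen pairs
while time remains; coalescence completes above the root. One lineage is
sampled per species (multiple accessions per taxon are modelled by the
many-to-one taxon map in the concordance stage, not by the coalescent).
Node times are root-to-tip depths measured from the tips, so species trees
are assumed ultrametric with contemporaneous tips — the package's own
generators only emit such trees.

`simulate_gene_tree_set()` adds per-(leaf, gene) dropout (emulating patchy
locus recovery; trees falling below 3 leaves are redrawn) and branch-support
values. Supports are simulation *metadata* — a constant (default 100) or a
uniform range used to exercise the support-threshold code paths — not
estimated bootstraps. Consequently a green simulated run establishes the
correctness of the bookkeeping (classification, tallies, thresholds) and the
coalescent distribution of topologies; it does **not** establish robustness
to alignment error, paralogy, gene-tree estimation error or support
miscalibration, none of which the generator models. Branch lengths are in
coalescent units; a `length_scale` factor converts them to
substitution-like scales for the branch-length-outlier tests.

The simulator is validated two independent ways: against the closed-form
quartet law above, and against msprime (an external coalescent simulator)
by a chi-square comparison of topology spectra on the same model.

# Concordance analysis

For each internal species-tree node with clade $C$ and a rooted gene tree
with taxon set $G$, let $R = C \cap G$. The gene tree is

- **uninformative** if $R$ has fewer than 2 taxa or no taxon of $G$ lies
  outside $R$ (the restricted clade is trivial), or if no sufficiently
  supported gene-tree clade matches or conflicts;
- **concordant** if some gene-tree clade with support $\ge$ `min_support`
  equals $R$;
- **conflicting** otherwise, if some such clade has non-empty intersection
  with, difference from, and complement-difference from $R$ (rooted clades
  are compatible iff nested or disjoint).

`min_support` defaults to 50, following the convention that branches below
50% bootstrap carry no information; low-support matches are deliberately
counted as uninformative rather than concordant, so the gray slice of a pie
chart aggregates "missing data" and "no signal".

Design choices made where the published tooling leaves the rule open:

- **Main-alternative reporting.** Among conflicting clades that meet the
  support threshold, the one with the smallest symmetric difference to $R$
  is reported (ties: higher support, then lexicographically smallest taxon
  set). The per-node "top alternative" is the modal such clade across gene
  trees, ties again broken lexicographically — every rule is deterministic
  so reruns are byte-identical.
- **Accession mapping.** Gene-tree tips map many-to-one onto species-tree
  taxa through an optional `taxon_map` before any set comparison; the
  default is the identity map.
- **Oracle.** The classifier is checked against a brute-force
  implementation (independent clade enumeration via `ape::prop.part`,
  direct set relations) on 1,000 random tree pairs in the test suite.

# Rooting and gene-tree sanitation

Rooted analyses require an outgroup: `reroot_on_outgroup()` roots on the
edge separating all present outgroup taxa from the ingroup, and refuses —
with a typed condition, so callers can tally reasons — when no outgroup is
present or when the present outgroups are not separable by one edge.
Refusing (rather than force-rooting on, say, the largest outgroup subset)
is the conservative choice: a non-monophyletic outgroup usually signals
contamination or misassembly, and silently picking a root would contaminate
every downstream per-node tally. Excluded trees simply drop out of the
rooted subset, mirroring how published pipelines end up analysing a reduced
tree set.

Branch-length outliers are flagged when a branch exceeds a fraction of the
total tree depth: 25% for terminal (ingroup pendant) branches, 50% for
internal branches, 75% for outgroup branches, the outgroup class taking
precedence. "Depth" is the maximum tip-to-tip path length by default; the
original description of this screen does not say whether tip-to-tip or
root-to-tip depth was meant, so both are provided (`depth_mode`), with
tip-to-tip the documented default because it is defined for unrooted gene
trees as inferred. Flagged branches are *reported, not auto-pruned* — the
workflow this mirrors reviewed each flag manually before removing
sequences, and `prune_leaves()` is provided for the removal step.

Low-support collapse contracts internal branches with support strictly
below 33 into polytomies. Absent support is treated as 0 and therefore
collapsible — conservative and easy to reason about in tests. The collapse
threshold (33) and the concordance support threshold (50) are deliberately
two independent parameters: the upstream convention collapses at 33 before
any downstream analysis, while concordance pies gray out branches below 50;
the package exposes both rather than reconciling them.

# Sequence and alignment QC

All length accounting uses ungapped residues, so a sequence's filtering
fate cannot depend on which alignment it happens to sit in. Thresholds are
strict: a sequence at exactly 25% of the target length is retained, a gene
with exactly 15 sequences is retained, a column at exactly 50% occupancy is
kept, support exactly 33 survives collapse. Boundary tests pin each of
these.

Codon threading maps each amino-acid column to one codon column (gap
`-` becomes `---`), after stripping a terminal stop codon when the protein
lacks a terminal `*`/`X` — the pal2nal-style tolerance for the most common
CDS/protein mismatch. Rows that still mismatch are excluded individually
(recorded in `thread_errors`) so one bad sequence does not sink a gene.

Occupancy trimming treats `-` and `?` as gaps but `N`/`X` as occupied:
ambiguity is data of unknown state, missingness is absence, and conflating
them would let a run of `N`s delete columns other samples support. On codon
alignments, trimming operates on whole codon triples so the reading frame
survives; whether the original nucleotide-level trimming preserved frame is
unstated, so a per-column mode (`codon_aware = FALSE`) exists for
replicating that behaviour.

The chimeric-target merge takes the first reference's residue wherever
present, else the second's; the preference is arbitrary but deterministic,
and the published description does not state its merge rule.

# Quartets and monophyly

`quartet_vote()` works on *unrooted* induced quartets (via the four-point
condition on topological distances), so votes are invariant to rerooting.
With multi-taxon groups, all one-leaf-per-group combinations are enumerated
up to a cap of 500, beyond which 500 are sampled under a fixed, configurable
seed; the tree votes for its majority topology and abstains on an exact tie
(the published tooling does not restate its per-tree rule, so majority was
chosen as the least surprising). A topology is *dominant* when its
frequency reaches 1/3; a branch is flagged a hard polytomy when all three
frequencies lie within $\pm\varepsilon$ of 1/3, with $\varepsilon = 0.05$
as the default quantification of "roughly equal" — both facts are reported
when both hold.

Monophyly classification uses a strong/weak threshold of 75 (the figure
style it mirrors names no number; exposed as `strong_threshold`). For trees
flagged unrooted, both sides of every split are considered when looking for
the group clade, since the group may sit rootward of the stored
representation.

# Supermatrix

Concatenation fills absent samples with gaps, partitions by gene and codon
position with 1-based inclusive ranges and stride 3 (RAxML convention), and
is exactly invertible given the scheme (round-tripped in the tests).
"Variable site" counts columns with at least two distinct unambiguous
residues, excluding gaps and ambiguity codes — the source material does not
define the term, and this matches common practice; users replicating a
published count should be aware the with-ambiguity count can differ.

# Numerical and degenerate-input conventions

- Supports are normalised to a 0–100 scale at parse time; values all in
  $[0,1]$ are multiplied by 100 (mixed RAxML/ASTRAL conventions). A
  configurable switch also accepts RAxML-style `[support]` branch comments.
- Newick round trips preserve branch lengths to 10 significant digits.
- Degenerate inputs error early and specifically: zero-depth trees in the
  outlier screen, empty gene-tree lists in concordance, zero-vote quartets,
  trees that would be pruned below 2 leaves.
- All randomness flows through explicit seeds (`sim_config`, fixture
  generator, combination sampling); fixed seeds give byte-identical newick,
  FASTA and report output, asserted in the tests.

# Known limitations

- The simulator assumes one sampled lineage per species, contemporaneous
  tips, and no migration, hybridisation, or linked loci; sequences
  themselves are never evolved (fixture alignments are random, with planted
  violations, not phylogenetically informative).
- The concordance stage trusts the input supports; it does not re-estimate
  them.
- Reproducing a published study's headline numbers (matrix dimensions,
  per-node counts) requires that study's deposited alignments and trees,
  which are an external download; the pipeline accepts such files but none
  are bundled.
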