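Package: phyloconcord
Title: Gene-Tree Conflict, Concordance and Alignment QC for Target-Enrichment Phylogenomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-assembly toolkit for target-enrichment (HybSeq) phylogenomic
    studies. Provides sequence- and gene-level recovery filters, stop-codon
    masking and protein-guided codon threading with occupancy-based trimming,
    gene-tree sanitation (branch-length outlier detection, low-support branch
    collapse, outgroup rooting), PhyParts-style per-node concordance and
    conflict tallies against a species tree, DiscoVista-style
    quartet-frequency and genus-monophyly summaries, partitioned supermatrix
    construction, and a multispecies-coalescent gene-tree simulator (with
    taxon dropout and support-value models) so that every stage can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
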