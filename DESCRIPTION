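Package: substab
Title: Bootstrap Reliability and Subtree Stability for Neighbor-Joining Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the reliability of a phylogenetic tree inferred by
    neighbor joining on uncorrected p-distances with two complementary
    statistics: the classical Felsenstein bootstrap probability (Pb) of each
    interior branch, and the subtree stability (Ps), the bootstrap
    probability that a clade's sequences together with one closest-outgroup
    sequence reproduce the originally inferred subtree topology, averaged
    over all closest-outgroup candidates. Includes FASTA/relaxed-PHYLIP
    alignment I/O, p-distance matrices with complete or pairwise deletion,
    topology algebra (bipartitions, rooting, induced subtrees), a seeded
    Jukes-Cantor sequence simulator for validation, and a deterministic
    end-to-end pipeline writing annotated Newick, a per-clade table, and a
    JSON audit trail.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
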