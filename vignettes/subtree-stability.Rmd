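---
title: "Branch reliability and subtree stability for NJ trees"
author: "substab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch reliability and subtree stability for NJ trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substab)
```

## The problem

The reliability of a phylogenetic tree inferred from sequence data is
conventionally summarised by the bootstrap probability of each interior
branch, here written Pb: the percentage of column-resampled replicates of
the alignment whose re-inferred tree contains the branch's bipartition of
the full taxon set. A high Pb for a branch, however, only says that the
*partition* of all sequences at that branch is stable. It does not say that
the *subtree* hanging off the branch — the internal arrangement a reader
actually looks at — would be recovered again. Deep clades with many
near-simultaneous divergences routinely combine a high Pb with a fragile
internal structure.

`substab` therefore computes a second, complementary statistic for each
clade, the subtree stability Ps. For a clade `C` of the inferred tree with
closest outgroup `o` (a leaf of `C`'s sister group), each bootstrap
replicate resamples alignment columns, restricts the alignment to
`C ∪ {o}`, re-infers a tree from p-distances by neighbor joining, and asks
whether that tree matches the original subtree, i.e. the induced subtree of
the full inferred tree on `C ∪ {o}`. With `s` matching replicates out of
`N`,

> Ps = (s / N) × 100%.

When the sister group contains several leaves, any of them is a closest
outgroup; `substab` runs the test once per candidate and reports the
unweighted arithmetic mean of the unrounded per-outgroup Ps values
(rounding happens only at display time). A subtree is only trustworthy when
*both* Pb and Ps are high.

Two kinds of clade get no Ps. A two-leaf clade always reproduces itself, so
its Ps carries no information and is reported `NA`. A clade whose parent is
the root has no sister group inside the analysis — its "outgroup" is the
rooting taxon itself — and is reported `NA` with reason `no-outgroup`
rather than silently dropped.

## The inference pipeline

The tree is built by neighbor joining on uncorrected p-distances (the
proportion of differing sites among compared columns), the classic "NJp"
workflow. The pipeline is:

1. read and validate the alignment (FASTA or relaxed PHYLIP);
2. filter columns (see *Missing data* below) — once, globally, **before**
   any resampling, so every replicate draws from the same well-defined
   column universe;
3. compute the p-distance matrix and the NJ tree (`ape::nj`, the C
   implementation of Saitou–Nei with the Studier–Keppler Q criterion;
   negative branch-length estimates are clamped to zero for output,
   without touching the topology);
4. root at the user-supplied outgroup to read off the clades;
5. compute Pb for every interior branch and Ps for every eligible clade;
6. write the annotated Newick (`Pb|Ps` internal labels), per-clade table,
   JSON audit with every per-outgroup `(s, N, ps)`, and a log.

Topology comparison is always unrooted and length-blind: two trees are "the
same" iff their sets of nontrivial bipartitions coincide (Robinson–Foulds
distance zero). "The subtree is recovered given the outgroup" is thus
reduced to identity of unrooted topologies on `C ∪ {o}`, which is exactly
what re-inferring an unrooted tree on the subset tests.

## Parameters that matter

* `replicates` (default **1000**): the bootstrap sample size for Pb and for
  each per-outgroup Ps run. Support values have resolution
  `100/replicates`. Below 500 the package warns that the estimate is
  coarse; the floor is 1.
* `deletion` (default **complete**): missing-data policy. `complete`
  removes every column containing a gap, `N` or IUPAC ambiguity code in
  *any* row before anything else; all pairs then share the same columns and
  the bootstrap universe is fixed. `pairwise` keeps all columns and skips
  unusable ones per pair; it preserves more signal for gappy data, but a
  replicate can then leave some pair with zero comparable columns. Such a
  degenerate replicate is counted in `N` and never in `s` (and counts as
  supporting no branch, for Pb), and is tallied in the log — silently
  dropping it would bias the denominators.
* `root_outgroup`: the rooting defines what counts as a clade. There is no
  canonical choice, so the tool asks for one; if none is given it roots at
  the leaf with the greatest mean p-distance to all others and says so.
  This heuristic is a pragmatic stand-in for biological knowledge, not a
  recommendation.
* `identity_bootstrap`: replaces every column draw by the identity. Every
  replicate then reproduces the original distance matrix, so every Pb and
  every eligible Ps must be exactly 100. This is an end-to-end self-check
  wired through the real code path, not an analysis mode. (Its Ps half
  additionally relies on NJ re-inference on a taxon subset reproducing the
  induced subtree on the original data; that holds on data with ordinary
  signal but is not a theorem for arbitrary distance matrices.)

## Reproducibility

Every replicate's column draw is seeded by a 31-bit hash of the master
seed, a stream key (`"pb"`, or `"ps:<clade>><outgroup>"`), and the
replicate index. Consequences: the same configuration gives byte-identical
outputs; per-(clade, outgroup) streams are independent; and the result for
a clade does not depend on which other clades are evaluated, or in what
order. The output files carry no timestamps, so determinism is testable by
byte comparison.

## The synthetic-data generator

`simulate_alignment()` evolves sequences along a tree under Jukes–Cantor
(JC69): the root sequence is i.i.d. uniform on {A,C,G,T}; along a branch of
length `t` (expected substitutions/site) each site changes with probability
`(3/4)(1 − e^(−4t/3))` and, given a change, moves uniformly to one of the
other three bases. `caterpillar_tree()` builds the ladder topology that
mimics deep gene-family trees with nested clades.

Validation uses an 8-leaf caterpillar with all branches at 0.05
substitutions/site, 5,000 sites and 200 replicates: large enough that every
true clade should reach Pb ≥ 95 and Ps ≥ 95, small enough to run in
seconds. The simulator deliberately omits rate heterogeneity across sites,
indels, base-composition bias and recombination; passing tests on it show
the machinery is correct and calibrated, not that real MHC-like data are
this well behaved. Calibration is checked against the closed form: two
leaves at total path 0.75 must show an empirical p-distance within ±0.03 of
`(3/4)(1 − e^(−1)) ≈ 0.474` at 10,000 sites.

## Numerical and design choices

* **`N` is the requested replicate count.** Every replicate of the subtree
  test builds *some* unrooted tree on the subset, so `N` is simply the
  number of replicates run for that clade/outgroup, and `s` the number that
  match. The alternative — conditioning `N` on the clade's monophyly in
  full-tree replicates — would contradict the subset procedure and make
  denominators random.
* **The reference topology is the induced subtree of the original full
  tree**, not a re-inferred subset tree: the question is whether replicates
  reproduce *the* inferred subtree, not some other one.
* **Averaging before rounding.** Per-outgroup Ps values are averaged
  unrounded; display rounds last.
* **Ties.** `ape::nj` breaks Q-criterion ties deterministically, so repeat
  runs and platforms agree; on fully degenerate input (an all-zero matrix)
  it returns an arbitrary but fixed binary resolution with zero lengths.
* **Degenerate input contracts.** Unequal row lengths, duplicate or empty
  taxon names, unknown symbols (with position), asymmetric matrices,
  zero-overlap pairs, and all-gap column sets all fail fast with the
  offending item named.

## Known limitations

* **p-distances are not additive**, and NJ on them can resolve a genuinely
  unresolved (zero-length) branching *systematically*: on the 8-leaf
  caterpillar with one internal branch collapsed to zero, NJ applied to the
  *expected* p-distance matrix already picks a particular resolution with a
  small positive artifact branch (~0.002–0.003). With enough sites the
  bootstrap then gives that artifactual branch a Pb near 100 — while its
  Ps stays low, because the subset replicates keep disagreeing about the
  region. This is a concrete instance of the method's central message: a
  high Pb alone, under the NJp model, can manufacture confidence where
  there is no signal, and the stability statistic is the one that notices.
  The bipartition that was actually collapsed, by contrast, receives a very
  low Pb (it can be scored even when absent from the inferred tree via
  `branch_support(extra_splits = )`).
* Ps cost grows as (eligible clades) × (outgroup candidates) × replicates
  NJ runs on small matrices; for trees with large sister groups consider
  fewer replicates first, never a subset of outgroup candidates, which
  would change the estimand.
* Ps is defined only for clades of the inferred rooted tree with a
  nonempty sister group; hypotheses about non-clades are out of scope.
* Only nucleotide data and only the NJp inference route are implemented;
  Pb and Ps are well-defined for any tree-building method, and the
  bootstrap engine takes the inference function as a fixed internal
  component by design, but no other method is wired in.
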