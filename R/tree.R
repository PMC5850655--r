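# Tree construction and topology algebra on ape "phylo" objects. Every
# topology comparison in the package reduces to canonical nontrivial
# bipartitions (splits): two unrooted trees on the same leaves are "the same
# topology" iff their split sets coincide (Robinson-Foulds distance 0).

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard Saitou-Nei neighbor joining (Studier-Keppler Q criterion, via
#' \code{\link[ape]{nj}}). Negative estimated branch lengths are clamped to
#' zero in the returned tree; the topology is whatever the Q criterion
#' selected. With exactly 3 taxa the unique unrooted star is returned with
#' three-point branch lengths.
#'
#' @param dm A `substab_dist` object, or a symmetric numeric matrix with taxa
#'   as dimnames.
#' @return An unrooted `phylo` tree on the taxa of `dm`.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "substab_dist")) dm$d else as.matrix(dm)
  if (is.null(rownames(d))) stop("distance matrix must carry taxon names")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric (tolerance 1e-12)")
  }
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (n == 3) {
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    v <- pmax(v, 0)
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   rownames(d)[1], v[1], rownames(d)[2], v[2], rownames(d)[3], v[3])
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Canonical key of one split relative to a full leaf set: the sorted side
# that does NOT contain the lexicographically smallest leaf, joined with a
# separator that cannot occur in taxon names we compare.
.split_key <- function(side, all_taxa) {
  ref <- min(all_taxa)
  s <- if (ref %in% side) setdiff(all_taxa, side) else side
  paste(sort(s), collapse = "\x1f")
}

# Canonical nontrivial split keys of a tree, treated as unrooted.
split_keys <- function(phy) {
  labs <- phy$tip.label
  if (length(labs) < 4) return(character(0))
  phy <- ape::unroot(phy)
  pp <- ape::prop.part(phy)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) >= 2 && length(labs) - length(side) >= 2) {
      keys <- c(keys, .split_key(side, labs))
    }
  }
  unique(keys)
}

.key_to_taxa <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

#' Nontrivial bipartitions of a tree
#'
#' One canonical split per interior branch of the unrooted tree: removing
#' the branch partitions the leaves into `side_a` (containing the
#' lexicographically smallest leaf) and `side_b`. An unrooted binary tree on
#' n leaves has exactly n - 3 of them.
#'
#' @param t A `phylo` tree with at least 4 leaves.
#' @return A list of splits, each a list with sorted character vectors
#'   `side_a` and `side_b`.
#' @export
bipartitions <- function(t) {
  if (length(t$tip.label) < 4) stop("bipartitions need at least 4 leaves")
  labs <- t$tip.label
  lapply(split_keys(t), function(k) {
    b <- .key_to_taxa(k)
    list(side_a = sort(setdiff(labs, b)), side_b = sort(b))
  })
}

#' Are two trees the same unrooted topology?
#'
#' True iff the trees share an identical set of nontrivial bipartitions
#' (equivalently, Robinson-Foulds distance zero). Branch lengths and
#' rootings are ignored.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return Logical scalar.
#' @export
same_topology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  setequal(split_keys(t1), split_keys(t2))
}

#' Root a tree on the branch leading to an outgroup leaf
#'
#' @param t A `phylo` tree.
#' @param outgroup A leaf label of `t`.
#' @return A rooted `phylo` whose root has two children: the outgroup leaf
#'   and everything else.
#' @export
root_at <- function(t, outgroup) {
  if (!outgroup %in% t$tip.label) {
    stop(sprintf("outgroup taxon not in tree: '%s'", outgroup))
  }
  ape::root(ape::unroot(t), outgroup = outgroup, resolve.root = TRUE)
}

#' Induced subtree on a taxon subset
#'
#' Prunes all other leaves and suppresses the resulting degree-2 vertices;
#' the split set of the result is the restriction of the tree's splits to
#' `taxa`.
#'
#' @param t A `phylo` tree.
#' @param taxa At least 3 leaf labels of `t`.
#' @return An unrooted `phylo` on exactly `taxa`.
#' @export
induced_subtree <- function(t, taxa) {
  if (length(taxa) < 3) stop("induced subtree needs at least 3 taxa")
  missing <- setdiff(taxa, t$tip.label)
  if (length(missing)) stop(sprintf("taxon not in tree: '%s'", missing[1]))
  ape::unroot(ape::keep.tip(ape::unroot(t), taxa))
}

#' Parse a Newick string
#'
#' @param text A Newick tree description.
#' @return A `phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop(sprintf("malformed Newick string: %s", substr(text, 1, 60)))
  tr
}

#' Format a support label for an interior branch
#'
#' The annotated Newick dialect writes `Pb|Ps` on internal nodes, with `NA`
#' where the stability value is undefined (two-taxon clades, or clades with
#' no outgroup).
#'
#' @param pb Bootstrap probability, percent.
#' @param ps Subtree stability, percent, or `NA`.
#' @param digits Rounding used for display.
#' @return A character scalar such as `"97|100"` or `"100|NA"`.
#' @export
format_support_label <- function(pb, ps, digits = 0) {
  fmt <- function(v) {
    if (is.null(v) || length(v) == 0 || is.na(v)) "NA"
    else format(round(v, digits), trim = TRUE, scientific = FALSE)
  }
  paste0(fmt(pb), "|", fmt(ps))
}

#' Write a tree as Newick
#'
#' With `annotation = "pb"` or `"pb_ps"`, interior-branch support values are
#' written as internal node labels (`Pb` alone, or the `Pb|Ps` dialect).
#' Support values are looked up from `pb` / `ps`, named vectors keyed by the
#' sorted, comma-joined leaf set of each clade.
#'
#' @param t A `phylo` tree (rooted, if annotations are attached to clades).
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @param annotation `"none"`, `"pb"` or `"pb_ps"`.
#' @param pb,ps Named numeric vectors of percent supports (see above).
#' @param digits Rounding for display labels.
#' @return The Newick string (invisibly if written to file).
#' @export
write_newick <- function(t, file = NULL, annotation = c("none", "pb", "pb_ps"),
                         pb = NULL, ps = NULL, digits = 0) {
  annotation <- match.arg(annotation)
  if (annotation != "none") {
    nt <- length(t$tip.label)
    labs <- character(t$Nnode)
    for (node in seq_len(t$Nnode)) {
      tips <- sort(clade_tips(t, nt + node))
      key <- paste(tips, collapse = ",")
      pbv <- if (!is.null(pb) && key %in% names(pb)) pb[[key]] else NA_real_
      psv <- if (!is.null(ps) && key %in% names(ps)) ps[[key]] else NA_real_
      if (length(tips) == nt || (is.na(pbv) && is.na(psv))) {
        labs[node] <- ""
      } else if (annotation == "pb") {
        labs[node] <- if (is.na(pbv)) "" else
          format(round(pbv, digits), trim = TRUE, scientific = FALSE)
      } else {
        labs[node] <- format_support_label(pbv, psv, digits)
      }
    }
    t$node.label <- labs
  }
  txt <- ape::write.tree(t)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Leaf labels under one node of a phylo tree.
clade_tips <- function(phy, node) {
  nt <- length(phy$tip.label)
  if (node <= nt) return(phy$tip.label[node])
  phy$tip.label[ape::prop.part(phy)[[node - nt]]]
}
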