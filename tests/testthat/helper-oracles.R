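# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths wherever they are
# used to check one: topology enumeration comes from phangorn::allTrees,
# tree comparison from phangorn::RF.dist, and distances from a naive
# column-by-column counter.

# Brute-force p-distance between two character vectors: loop over columns,
# count sites where both symbols are plain bases and where they differ.
brute_p_distance <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  m <- 0L; diff <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% bases && b[k] %in% bases) {
      m <- m + 1L
      if (a[k] != b[k]) diff <- diff + 1L
    }
  }
  list(p = if (m > 0) diff / m else NA_real_, m = m)
}

# Least-squares fit of branch lengths of a fixed topology to a distance
# matrix; returns the residual sum of squares. Edge indicator: an edge lies
# on the i-j path iff exactly one of i,j is below it.
ls_fit_ss <- function(topo, d) {
  labs <- topo$tip.label
  nt <- length(labs)
  pairs <- t(combn(nt, 2))
  A <- matrix(0, nrow(pairs), nrow(topo$edge))
  below <- vector("list", nt + topo$Nnode)
  for (v in seq_len(nt)) below[[v]] <- v
  topo2 <- stats::reorder(topo, "postorder")
  for (e in seq_len(nrow(topo2$edge))) {
    par <- topo2$edge[e, 1]; ch <- topo2$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  for (e in seq_len(nrow(topo$edge))) {
    S <- below[[topo$edge[e, 2]]]
    inS <- matrix(pairs %in% S, nrow(pairs), 2)
    A[, e] <- xor(inS[, 1], inS[, 2])
  }
  dv <- d[labs, labs][pairs]
  fit <- stats::lm.fit(A, dv)
  sum(fit$residuals^2)
}

# Exhaustive search: the unrooted topology (among all of them) whose
# least-squares fit to `d` is best. Feasible for up to ~7 taxa.
best_ls_topology <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  ss <- vapply(topos, ls_fit_ss, 0, d = d)
  topos[[which.min(ss)]]
}

# Random unrooted binary tree with branch lengths bounded away from zero,
# and its additive (path-length) distance matrix.
random_additive <- function(n, min_len = 0.05, max_len = 0.5) {
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Random alignment over bases plus optional gap/ambiguity symbols.
random_alignment <- function(n_taxa, n_sites, gap_frac = 0) {
  syms <- c("A", "C", "G", "T")
  mat <- matrix(sample(syms, n_taxa * n_sites, replace = TRUE), n_taxa, n_sites)
  if (gap_frac > 0) {
    k <- ceiling(gap_frac * length(mat))
    mat[sample(length(mat), k)] <- sample(c("-", "N", "R"), k, replace = TRUE)
  }
  rownames(mat) <- sprintf("x%02d", seq_len(n_taxa))
  alignment(mat)
}

# A gap-containing alignment with clear tree signal: JC69 simulation with a
# few percent of symbols overwritten by gaps/ambiguities.
gappy_signal_alignment <- function(n_leaves = 6, n_sites = 800, seed = 11,
                                   gap_frac = 0.03) {
  tr <- caterpillar_tree(n_leaves, 0.08, 0.08)
  aln <- simulate_alignment(tr, n_sites, seed = seed)
  mat <- aln$mat
  set.seed(seed + 1)
  k <- ceiling(gap_frac * length(mat))
  mat[sample(length(mat), k)] <- sample(c("-", "N"), k, replace = TRUE)
  alignment(mat)
}

# An alternative representation of the same unrooted topology (rerooted at
# a random leaf, then unrooted again).
rerepresent <- function(tr) {
  og <- sample(tr$tip.label, 1)
  ape::unroot(ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Set to zero the internal branch whose child subtends exactly `clade`.
zero_branch_above <- function(tree, clade) {
  nt <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  node <- NA
  for (k in seq_along(pp)) {
    if (setequal(tree$tip.label[pp[[k]]], clade)) node <- nt + k
  }
  stopifnot(!is.na(node))
  e <- which(tree$edge[, 2] == node)
  stopifnot(length(e) == 1)
  tree$edge.length[e] <- 0
  tree
}

# Stability results for the clades resolving an ambiguous (zero-length)
# region: eligible clades whose defining split is not among the strongly
# supported true splits; if the realized resolution produced no such
# eligible clade (e.g. a two-taxon clade), fall back to the smallest
# eligible clade containing the region, whose internal resolution is then
# the ambiguous part.
ambiguous_clades <- function(stab, strong_keys, region) {
  elig <- Filter(function(s) !is.na(s$ps_mean), stab)
  novel <- Filter(function(s) !(s$key %in% strong_keys), elig)
  if (length(novel)) return(novel)
  containing <- Filter(function(s) all(region %in% s$clade_taxa), elig)
  if (!length(containing)) return(list())
  sizes <- sapply(containing, function(s) length(s$clade_taxa))
  containing[sizes == min(sizes)]
}

# Rooting-heuristic oracle: leaf with greatest mean p-distance, computed by
# the brute-force pair counter.
farthest_by_hand <- function(aln) {
  n <- length(aln$taxa)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- brute_p_distance(aln$mat[i, ], aln$mat[j, ])$p
  }
  aln$taxa[which.max(rowMeans(d))]
}
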