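# Jukes-Cantor (JC69) sequence simulation along a tree with known branch
# lengths, for building test data with a known true topology. The root
# sequence is i.i.d. uniform over {A,C,G,T}; along a branch of length t
# (expected substitutions/site) each site changes with probability
# (3/4)(1 - exp(-4t/3)) and, given a change, moves to one of the other
# three bases uniformly. No rate heterogeneity, no indels.

#' Ladder ("caterpillar") tree
#'
#' The rooted ladder topology `(((...((t1,t2),t3)...),tn)`: each new leaf
#' attaches above all previous ones. Mirrors the shape of deep gene-family
#' trees where stability of large nested clades is at stake.
#'
#' @param n_leaves Number of leaves (at least 4).
#' @param internal_len Length of every internal branch (substitutions/site).
#' @param terminal_len Length of every terminal branch.
#' @param labels Optional leaf labels; default `t1 ... tn`.
#' @return A rooted `phylo` with branch lengths.
#' @export
caterpillar_tree <- function(n_leaves, internal_len = 0.05, terminal_len = 0.05,
                             labels = NULL) {
  if (n_leaves < 4) stop("caterpillar tree needs at least 4 leaves")
  labels <- labels %||% paste0("t", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves)
  txt <- sprintf("(%s:%.10g,%s:%.10g)", labels[1], terminal_len,
                 labels[2], terminal_len)
  for (k in 3:n_leaves) {
    txt <- sprintf("(%s:%.10g,%s:%.10g)", txt, internal_len, labels[k], terminal_len)
  }
  ape::read.tree(text = paste0(txt, ";"))
}

#' Simulate an alignment under JC69
#'
#' @param tree A `phylo` with nonnegative branch lengths; leaves become the
#'   alignment taxa.
#' @param n_sites Number of alignment columns.
#' @param seed Integer seed; the same seed reproduces the alignment exactly.
#' @return A `substab_aln` of the leaf sequences.
#' @examples
#' tr <- caterpillar_tree(5, 0.05, 0.05)
#' aln <- simulate_alignment(tr, 200, seed = 1)
#' @export
simulate_alignment <- function(tree, n_sites, seed = 1) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in simulation tree")
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise") # parents before children
  with_seed(seed, {
    seqs <- matrix(NA_integer_, nt + tree$Nnode, n_sites)
    root <- tree$edge[1, 1]
    seqs[root, ] <- sample.int(4L, n_sites, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      p_change <- 0.75 * (1 - exp(-4 * t / 3))
      s <- seqs[par, ]
      hit <- which(stats::runif(n_sites) < p_change)
      if (length(hit)) {
        # uniform over the three other bases
        s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      seqs[child, ] <- s
    }
    mat <- matrix(BASES[seqs[seq_len(nt), , drop = FALSE]], nt, n_sites)
    rownames(mat) <- tree$tip.label
    alignment(mat)
  })
}
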