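# Felsenstein bootstrap over alignment columns, and Pb for every interior
# branch of the inferred tree. Each replicate resamples columns of the
# (globally gap-filtered, under complete deletion) alignment, rebuilds the
# p-distance matrix and the NJ tree, and is scored against the splits of the
# original tree. Every replicate's column draw is seeded from
# (seed, stream key, replicate index), so results do not depend on the order
# in which replicates -- or whole clades -- are evaluated.

#' Bootstrap column resampling
#'
#' Draws `n_sites` column indices uniformly with replacement, from a stream
#' fully determined by `seed`. Used for both the full-tree bootstrap (Pb)
#' and the per-clade subtree bootstrap (Ps).
#'
#' @param n_sites Number of alignment columns (and of indices drawn).
#' @param seed Integer sub-seed for this replicate.
#' @return An integer vector of length `n_sites` with values in
#'   `1:n_sites`.
#' @export
resample_columns <- function(n_sites, seed) {
  stopifnot(n_sites >= 1)
  with_seed(seed, sample.int(n_sites, n_sites, replace = TRUE))
}

check_replicates <- function(replicates) {
  if (replicates < 1) stop("replicates must be at least 1")
  if (replicates < 500) {
    warning(sprintf(
      "only %d bootstrap replicates requested; 500 or more are recommended for accurate support values",
      replicates), call. = FALSE)
  }
  invisible(replicates)
}

# Shared replicate engine: given pair profiles (already restricted to the
# relevant taxa and, under complete deletion, to gap-free columns), run
# `replicates` bootstrap NJ trees and hand each to `score(tree)`; a
# degenerate replicate (a taxon pair with no usable column after resampling,
# pairwise mode only) is handed as NULL. Column draws come from
# mix_seed(seed, key, r).
bootstrap_replicates <- function(prof, replicates, seed, key,
                                 identity_bootstrap = FALSE,
                                 all_valid = TRUE, score) {
  L <- ncol(prof$diff)
  for (r in seq_len(replicates)) {
    idx <- if (identity_bootstrap) seq_len(L) else
      resample_columns(L, mix_seed(seed, key, r))
    d <- profile_dist(prof, idx, all_valid = all_valid)
    score(if (is.null(d)) NULL else neighbor_joining(d))
  }
}

#' Bootstrap probability (Pb) of every interior branch
#'
#' The classical bootstrap support: the percentage of replicates, each a
#' column resample of the full alignment re-analysed by NJ on p-distances,
#' whose tree contains a given interior branch's bipartition.
#'
#' @param aln A `substab_aln` (the full alignment).
#' @param tree The tree inferred from `aln` (unrooted `phylo`).
#' @param replicates Number of bootstrap replicates (default 1000; below 500
#'   a warning recommends more).
#' @param seed Integer seed; the same seed reproduces the Pb vector exactly.
#' @param deletion Gap handling, as in [distance_matrix()]. Complete deletion
#'   is applied once, before resampling, so replicates draw only from
#'   retained columns.
#' @param identity_bootstrap If `TRUE`, every replicate reuses the original
#'   columns instead of resampling; all supports are then 100 by
#'   construction (a pipeline self-check, not an analysis mode).
#' @param extra_splits Optional list of character vectors, each a
#'   hypothesized clade (one side of a bipartition, 2 to n-2 taxa): its
#'   bootstrap support is scored from the same replicate trees even if the
#'   inferred tree does not contain it.
#' @return A data frame with one row per interior branch (plus one per extra
#'   split): `clade` (the smaller split side, comma-joined), `size`, `pb`,
#'   `replicates`. Attribute `"failed"` counts degenerate replicates (scored
#'   as supporting nothing).
#' @export
branch_support <- function(aln, tree, replicates = 1000, seed = 1,
                           deletion = c("complete", "pairwise"),
                           identity_bootstrap = FALSE, extra_splits = NULL) {
  deletion <- match.arg(deletion)
  check_replicates(replicates)
  if (!setequal(aln$taxa, tree$tip.label)) {
    stop("alignment taxa and tree leaves differ")
  }
  keys <- split_keys(tree)
  if (!is.null(extra_splits)) {
    for (side in extra_splits) {
      if (length(side) < 2 || length(setdiff(tree$tip.label, side)) < 2 ||
          length(setdiff(side, tree$tip.label))) {
        stop("each extra split must name 2 to n-2 leaves of the tree")
      }
      keys <- union(keys, .split_key(side, tree$tip.label))
    }
  }
  x <- code_alignment(aln)
  if (deletion == "complete") {
    keep <- complete_columns(x)
    if (!length(keep)) stop("complete deletion removed every column: no gap-free sites")
    x <- x[, keep, drop = FALSE]
  }
  prof <- pair_profiles(x)
  counts <- stats::setNames(integer(length(keys)), keys)
  failed <- 0L
  bootstrap_replicates(prof, replicates, seed, key = "pb",
                       identity_bootstrap = identity_bootstrap,
                       all_valid = (deletion == "complete"),
                       score = function(tr) {
                         if (is.null(tr)) {
                           failed <<- failed + 1L
                         } else {
                           hit <- keys %in% split_keys(tr)
                           counts[hit] <<- counts[hit] + 1L
                         }
                       })
  labs <- tree$tip.label
  sides <- lapply(keys, function(k) {
    b <- .key_to_taxa(k)
    a <- setdiff(labs, b)
    a <- sort(a); b <- sort(b)
    if (length(a) < length(b)) a
    else if (length(b) < length(a)) b
    else if (paste(a, collapse = ",") <= paste(b, collapse = ",")) a else b
  })
  out <- data.frame(
    clade = vapply(sides, paste, "", collapse = ","),
    size = lengths(sides),
    pb = 100 * as.numeric(counts) / replicates,
    replicates = replicates,
    stringsAsFactors = FALSE
  )
  out$key <- keys
  attr(out, "failed") <- failed
  out
}
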