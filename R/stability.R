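# Subtree stability (Ps): for each clade of the rooted inferred tree, the
# bootstrap probability that the clade's sequences plus ONE closest-outgroup
# sequence, re-analysed from column resamples, reproduce the originally
# inferred subtree topology. Where the sister group offers several outgroup
# candidates, Ps is computed once per candidate and averaged (unweighted,
# unrounded). Two-taxon clades always reproduce themselves and get no Ps;
# a clade whose parent is the root has no outgroup and gets no Ps either.

#' Enumerate the clades of a rooted tree
#'
#' One record per internal vertex below the root. Each record carries the
#' clade's leaf set, its defining split in the full tree, its sister group
#' (the other child of its parent -- the closest-outgroup candidate pool;
#' empty when the clade is a child of the root), and whether the clade is
#' eligible for a stability value (at least 3 leaves and a nonempty sister).
#'
#' @param rooted A rooted binary `phylo` on at least 4 leaves.
#' @return A list of clade records (`clade_taxa`, `sister_taxa`, `key`,
#'   `eligible`, `reason`), ordered by increasing clade size then
#'   lexicographically.
#' @export
enumerate_clades <- function(rooted) {
  if (!ape::is.rooted(rooted)) {
    stop("tree is unrooted: root it first (see root_at)")
  }
  nt <- length(rooted$tip.label)
  if (nt < 4) stop("clade enumeration needs at least 4 leaves")
  labs <- rooted$tip.label
  pp <- ape::prop.part(rooted)
  root <- nt + 1L
  parent <- integer(nt + rooted$Nnode)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  tips_of <- function(node) {
    if (node <= nt) labs[node] else labs[pp[[node - nt]]]
  }
  recs <- list()
  for (node in (nt + 1L):(nt + rooted$Nnode)) {
    if (node == root) next
    clade <- sort(tips_of(node))
    par <- parent[node]
    sibs <- rooted$edge[rooted$edge[, 1] == par, 2]
    sibs <- sibs[sibs != node]
    sister <- if (par == root) character(0) else
      sort(unlist(lapply(sibs, tips_of), use.names = FALSE))
    eligible <- length(clade) >= 3 && length(sister) > 0
    reason <- if (eligible) NA_character_
      else if (length(clade) < 3) "two-taxon"
      else "no-outgroup"
    recs[[length(recs) + 1]] <- list(
      clade_taxa = clade,
      sister_taxa = sister,
      key = .split_key(clade, labs),
      eligible = eligible,
      reason = reason
    )
  }
  ord <- order(vapply(recs, function(r) length(r$clade_taxa), 0L),
               vapply(recs, function(r) paste(r$clade_taxa, collapse = ","), ""))
  recs[ord]
}

#' Closest-outgroup candidates of a clade
#'
#' All leaves of the clade's sister group (the other child of its parent in
#' the rooted tree), sorted lexicographically. Any of them is "a closest
#' outgroup" for the stability test; [ps_averaged()] uses each in turn.
#'
#' @param rec A clade record from [enumerate_clades()].
#' @return Character vector of taxon names (possibly empty for a child of
#'   the root).
#' @export
closest_outgroups <- function(rec) {
  sort(rec$sister_taxa)
}

# Shared precomputation for the subtree bootstrap of one clade+outgroup set:
# restrict the (already filtered) coded alignment and build pair profiles.
subset_profiles <- function(x, taxa) {
  pair_profiles(x[taxa, , drop = FALSE])
}

ps_stream_key <- function(clade_taxa, outgroup) {
  paste0("ps:", paste(sort(clade_taxa), collapse = ","), ">", outgroup)
}

# Core single-outgroup loop over prepared inputs; exposed wrapper below.
.ps_single <- function(x, full_tree, clade_taxa, outgroup, replicates, seed,
                       all_valid, identity_bootstrap) {
  taxa <- c(sort(clade_taxa), outgroup)
  ref <- induced_subtree(full_tree, taxa)
  ref_keys <- split_keys(ref)
  prof <- subset_profiles(x, taxa)
  s <- 0L
  failed <- 0L
  bootstrap_replicates(prof, replicates, seed,
                       key = ps_stream_key(clade_taxa, outgroup),
                       identity_bootstrap = identity_bootstrap,
                       all_valid = all_valid,
                       score = function(tr) {
                         if (is.null(tr)) failed <<- failed + 1L
                         else if (setequal(split_keys(tr), ref_keys)) s <<- s + 1L
                       })
  list(outgroup = outgroup, s = s, N = replicates, ps = 100 * s / replicates,
       failed = failed)
}

# Prepare the coded, complete-deletion-filtered alignment once per run.
prepare_coded <- function(aln, deletion) {
  x <- code_alignment(aln)
  if (deletion == "complete") {
    keep <- complete_columns(x)
    if (!length(keep)) stop("complete deletion removed every column: no gap-free sites")
    x <- x[, keep, drop = FALSE]
  }
  x
}

#' Stability of one clade with one fixed closest outgroup
#'
#' Builds the reference topology as the induced subtree of the full inferred
#' tree on the clade plus the outgroup, then counts the bootstrap replicates
#' (column resamples of the globally filtered alignment, restricted to those
#' taxa, NJ on p-distances) whose tree matches it: `ps = 100 * s / N`.
#'
#' @param aln The full alignment (`substab_aln`).
#' @param full_tree The inferred full tree (unrooted `phylo`).
#' @param rec A clade record from [enumerate_clades()], with at least 3
#'   leaves.
#' @param outgroup One of `closest_outgroups(rec)`.
#' @param replicates,seed Bootstrap replicate count N and master seed.
#' @param deletion Gap handling, as in [distance_matrix()].
#' @param identity_bootstrap If `TRUE`, reuse original columns (self-check
#'   mode).
#' @return A list with `outgroup`, `s`, `N`, `ps` and `failed` (degenerate
#'   replicates, counted in N but never in s).
#' @export
ps_single_outgroup <- function(aln, full_tree, rec, outgroup,
                               replicates = 1000, seed = 1,
                               deletion = c("complete", "pairwise"),
                               identity_bootstrap = FALSE) {
  deletion <- match.arg(deletion)
  if (length(rec$clade_taxa) < 3) {
    stop("stability is undefined for two-taxon clades")
  }
  if (!outgroup %in% closest_outgroups(rec)) {
    stop(sprintf("'%s' is not a closest-outgroup candidate for this clade", outgroup))
  }
  x <- prepare_coded(aln, deletion)
  .ps_single(x, full_tree, rec$clade_taxa, outgroup, replicates, seed,
             all_valid = (deletion == "complete"), identity_bootstrap)
}

#' Outgroup-averaged stability of one clade
#'
#' Runs the single-outgroup stability test once per closest-outgroup
#' candidate, with independent deterministically derived replicate streams,
#' and averages the unrounded Ps values.
#'
#' @inheritParams ps_single_outgroup
#' @return A `StabilityResult`: list with `clade_taxa`, `per_outgroup` (data
#'   frame of `outgroup`, `s`, `N`, `ps`, `failed`) and `ps_mean`.
#' @export
ps_averaged <- function(aln, full_tree, rec, replicates = 1000, seed = 1,
                        deletion = c("complete", "pairwise"),
                        identity_bootstrap = FALSE) {
  deletion <- match.arg(deletion)
  if (!isTRUE(rec$eligible)) {
    stop(sprintf("clade is not eligible for a stability value (%s)",
                 rec$reason %||% "ineligible"))
  }
  x <- prepare_coded(aln, deletion)
  res <- lapply(closest_outgroups(rec), function(og) {
    .ps_single(x, full_tree, rec$clade_taxa, og, replicates, seed,
               all_valid = (deletion == "complete"), identity_bootstrap)
  })
  per <- do.call(rbind, lapply(res, function(r) {
    data.frame(outgroup = r$outgroup, s = r$s, N = r$N, ps = r$ps,
               failed = r$failed, stringsAsFactors = FALSE)
  }))
  list(clade_taxa = rec$clade_taxa, sister_taxa = rec$sister_taxa,
       key = rec$key, per_outgroup = per, ps_mean = mean(per$ps))
}

#' Stability profile of every eligible clade
#'
#' Enumerates the clades of the rooted inferred tree and computes the
#' outgroup-averaged stability for each eligible one (at least 3 leaves and
#' a nonempty sister group). Ineligible clades are reported with `ps_mean =
#' NA` and the reason.
#'
#' @param aln The full alignment.
#' @param full_tree The inferred full tree (unrooted `phylo`).
#' @param root_outgroup Leaf used to root the tree for clade enumeration; if
#'   `NULL`, the leaf with the greatest mean p-distance to all others is
#'   used and reported via a message.
#' @param replicates,seed,deletion,identity_bootstrap As in
#'   [ps_single_outgroup()].
#' @return A list of results, one per clade record (in the order of
#'   [enumerate_clades()]): eligible clades get the [ps_averaged()] result;
#'   ineligible ones get the record with `ps_mean = NA`.
#' @export
stability_profile <- function(aln, full_tree, root_outgroup = NULL,
                              replicates = 1000, seed = 1,
                              deletion = c("complete", "pairwise"),
                              identity_bootstrap = FALSE) {
  deletion <- match.arg(deletion)
  check_replicates(replicates)
  if (is.null(root_outgroup)) {
    dm <- distance_matrix(aln, deletion = deletion)
    root_outgroup <- farthest_leaf(dm)
    message(sprintf("no root outgroup given; rooting at '%s' (greatest mean p-distance)",
                    root_outgroup))
  }
  rooted <- root_at(full_tree, root_outgroup)
  recs <- enumerate_clades(rooted)
  x <- prepare_coded(aln, deletion)
  lapply(recs, function(rec) {
    if (!rec$eligible) {
      return(list(clade_taxa = rec$clade_taxa, sister_taxa = rec$sister_taxa,
                  key = rec$key, per_outgroup = NULL, ps_mean = NA_real_,
                  reason = rec$reason))
    }
    res <- lapply(closest_outgroups(rec), function(og) {
      .ps_single(x, full_tree, rec$clade_taxa, og, replicates, seed,
                 all_valid = (deletion == "complete"), identity_bootstrap)
    })
    per <- do.call(rbind, lapply(res, function(r) {
      data.frame(outgroup = r$outgroup, s = r$s, N = r$N, ps = r$ps,
                 failed = r$failed, stringsAsFactors = FALSE)
    }))
    list(clade_taxa = rec$clade_taxa, sister_taxa = rec$sister_taxa,
         key = rec$key, per_outgroup = per, ps_mean = mean(per$ps))
  })
}

# Leaf with the greatest mean p-distance to all others (rooting heuristic).
farthest_leaf <- function(dm) {
  means <- rowMeans(dm$d)
  dm$taxa[which.max(means)]
}
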