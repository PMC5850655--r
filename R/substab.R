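# The main entry point: alignment -> NJp tree -> Pb -> Ps -> classed fit
# object, plus the file-writing pipeline behind the command-line script.

#' Reliability and stability profile of a neighbor-joining tree
#'
#' Infers the NJ tree from p-distances, computes the bootstrap probability
#' (Pb) of every interior branch from full-alignment column resamples, and
#' the subtree stability (Ps) of every eligible clade: the bootstrap
#' probability that the clade's sequences plus one closest-outgroup sequence
#' reproduce the originally inferred subtree, averaged over all
#' closest-outgroup candidates. A tree is only trustworthy where both
#' statistics are high: Pb measures the branch as a partition of all
#' sequences, Ps whether the subtree itself would be recovered.
#'
#' @param x A `substab_aln`, or a path to a FASTA/PHYLIP alignment.
#' @param replicates Bootstrap replicates for both Pb and each per-outgroup
#'   Ps run (default 1000; below 500 a warning recommends more).
#' @param seed Integer master seed; all replicate streams derive from it.
#' @param deletion Gap handling, `"complete"` (default) or `"pairwise"`; see
#'   [distance_matrix()].
#' @param root_outgroup Leaf used to root the inferred tree for clade
#'   enumeration. If `NULL`, the leaf with the greatest mean p-distance is
#'   used and the choice is recorded.
#' @param identity_bootstrap If `TRUE`, replicates reuse the original
#'   columns; every Pb and every eligible Ps is then 100 by construction
#'   (end-to-end self-check).
#' @param format Alignment file format when `x` is a path.
#' @return An object of class `substab`: list with `tree` (unrooted inferred
#'   `phylo`), `rooted` (rooted for clade reading), `dist`, `pb` (branch
#'   support table), `stability` (per-clade results), `clade_table` (one row
#'   per interior branch), and `meta` (seed, replicates, deletion, rooting,
#'   degenerate-replicate counts).
#' @examples
#' aln <- simulate_alignment(caterpillar_tree(6), 500, seed = 7)
#' fit <- substab(aln, replicates = 100, seed = 7, root_outgroup = "t6")
#' summary(fit)
#' @export
substab <- function(x, replicates = 1000, seed = 1,
                    deletion = c("complete", "pairwise"),
                    root_outgroup = NULL, identity_bootstrap = FALSE,
                    format = "auto") {
  deletion <- match.arg(deletion)
  aln <- if (inherits(x, "substab_aln")) x else read_alignment(x, format = format)
  if (length(aln$taxa) < 4) stop("tree inference needs at least 4 taxa")
  check_replicates(replicates)

  dm <- distance_matrix(aln, deletion = deletion)
  tree <- neighbor_joining(dm)

  rooting <- "user"
  if (is.null(root_outgroup)) {
    root_outgroup <- farthest_leaf(dm)
    rooting <- "heuristic:max-mean-p-distance"
    message(sprintf("no root outgroup given; rooting at '%s' (greatest mean p-distance)",
                    root_outgroup))
  }
  rooted <- root_at(tree, root_outgroup)

  pb <- suppressWarnings(
    branch_support(aln, tree, replicates = replicates, seed = seed,
                   deletion = deletion, identity_bootstrap = identity_bootstrap))
  stab <- suppressWarnings(
    stability_profile(aln, tree, root_outgroup = root_outgroup,
                      replicates = replicates, seed = seed,
                      deletion = deletion, identity_bootstrap = identity_bootstrap))

  fit <- structure(list(
    alignment = aln, dist = dm, tree = tree, rooted = rooted,
    pb = pb, stability = stab,
    clade_table = build_clade_table(pb, stab),
    meta = list(
      n_taxa = length(aln$taxa), n_sites = aln$n_sites,
      n_sites_used = dm$n_sites_used,
      replicates = replicates, seed = seed, deletion = deletion,
      root_outgroup = root_outgroup, rooting = rooting,
      identity_bootstrap = identity_bootstrap,
      failed_pb_replicates = attr(pb, "failed"),
      failed_ps_replicates = sum(vapply(stab, function(s) {
        if (is.null(s$per_outgroup)) 0 else sum(s$per_outgroup$failed)
      }, 0)),
      version = as.character(utils::packageVersion("substab"))
    )
  ), class = "substab")
  fit
}

# One row per interior branch of the inferred tree: Pb always, Ps where
# eligible. Clades are matched to splits by canonical key; the child-of-root
# clade complementary to the root outgroup corresponds to a trivial split
# and is not a table row.
build_clade_table <- function(pb, stab) {
  stab_by_key <- stats::setNames(stab, vapply(stab, `[[`, "", "key"))
  rows <- lapply(seq_len(nrow(pb)), function(r) {
    key <- pb$key[r]
    s <- stab_by_key[[key]]
    if (!is.null(s) && !is.null(s$per_outgroup)) {
      data.frame(
        clade = paste(s$clade_taxa, collapse = ","),
        size = length(s$clade_taxa),
        pb = pb$pb[r],
        n_outgroups = nrow(s$per_outgroup),
        outgroups = paste(s$per_outgroup$outgroup, collapse = ","),
        ps_values = paste(format(round(s$per_outgroup$ps, 2), trim = TRUE),
                          collapse = ","),
        s_over_N = paste(sprintf("%d/%d", s$per_outgroup$s, s$per_outgroup$N),
                         collapse = ","),
        ps_mean = s$ps_mean,
        ps_reason = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      clade <- if (!is.null(s)) s$clade_taxa else .key_to_taxa(key)
      reason <- if (!is.null(s)) s$reason %||% "ineligible" else "not-a-clade"
      data.frame(
        clade = paste(sort(clade), collapse = ","),
        size = length(clade), pb = pb$pb[r],
        n_outgroups = 0L, outgroups = "", ps_values = "", s_over_N = "",
        ps_mean = NA_real_, ps_reason = reason,
        stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$key <- pb$key
  tab[order(tab$size, tab$clade), , drop = FALSE]
}

#' Annotated tree of a fit
#'
#' The rooted inferred tree with `Pb|Ps` internal node labels (the Fig.-style
#' display: branch bootstrap above, subtree stability below), `NA` where Ps
#' is undefined.
#'
#' @param fit A `substab` object.
#' @param digits Rounding for display.
#' @return A rooted `phylo` with `node.label` set.
#' @export
annotated_tree <- function(fit, digits = 0) {
  stopifnot(inherits(fit, "substab"))
  tab <- fit$clade_table
  # the table's clade column is the rooted clade's sorted comma-joined leaf
  # set, exactly the lookup key write_newick uses for node labels
  pb <- stats::setNames(tab$pb, tab$clade)
  ps <- stats::setNames(tab$ps_mean, tab$clade)
  txt <- write_newick(fit$rooted, annotation = "pb_ps", pb = pb, ps = ps,
                      digits = digits)
  parse_newick(txt)
}

#' @export
print.substab <- function(x, ...) {
  m <- x$meta
  cat("Subtree stability analysis (NJp bootstrap)\n")
  cat(sprintf("  %d taxa, %d sites (%d used after %s deletion)\n",
              m$n_taxa, m$n_sites, m$n_sites_used, m$deletion))
  cat(sprintf("  %d bootstrap replicates, seed %d, rooted at '%s' (%s)\n",
              m$replicates, m$seed, m$root_outgroup, m$rooting))
  if (isTRUE(m$identity_bootstrap)) cat("  [identity-bootstrap self-check mode]\n")
  eligible <- !is.na(x$clade_table$ps_mean)
  cat(sprintf("  %d interior branches; Pb range %s-%s; Ps computed for %d clades\n",
              nrow(x$clade_table),
              format(min(x$clade_table$pb)), format(max(x$clade_table$pb)),
              sum(eligible)))
  invisible(x)
}

#' @export
summary.substab <- function(object, ...) {
  structure(list(meta = object$meta, clade_table = object$clade_table),
            class = "summary.substab")
}

#' @export
print.summary.substab <- function(x, ...) {
  m <- x$meta
  cat(sprintf("NJp tree of %d taxa (%d sites used), %d replicates, seed %d\n",
              m$n_taxa, m$n_sites_used, m$replicates, m$seed))
  cat(sprintf("Rooted at '%s' (%s), %s deletion\n\n",
              m$root_outgroup, m$rooting, m$deletion))
  tab <- x$clade_table
  show <- data.frame(clade = tab$clade, size = tab$size,
                     Pb = round(tab$pb, 1),
                     Ps = ifelse(is.na(tab$ps_mean), NA, round(tab$ps_mean, 1)),
                     outgroups = tab$outgroups,
                     stringsAsFactors = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Plot an annotated stability tree
#'
#' Draws the rooted inferred tree with `Pb|Ps` labels on interior branches.
#'
#' @param x A `substab` object.
#' @param digits Label rounding.
#' @param ... Passed to \code{\link[ape]{plot.phylo}}.
#' @export
plot.substab <- function(x, digits = 0, ...) {
  tr <- annotated_tree(x, digits = digits)
  ape::plot.phylo(tr, ...)
  if (!is.null(tr$node.label)) {
    ape::nodelabels(tr$node.label, frame = "none", adj = c(1.1, -0.3), cex = 0.8)
  }
  invisible(x)
}
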