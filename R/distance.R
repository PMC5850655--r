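# p-distances: the uncorrected proportion of differing sites, the distance
# the NJp workflow feeds to neighbor joining. Gaps, N and IUPAC ambiguity
# codes are missing data: under complete deletion every column containing
# any such symbol in any row is removed once, globally, before anything else
# (including bootstrap resampling); under pairwise deletion each pair skips
# its own unusable columns.

BASES <- c("A", "C", "G", "T")

# Integer-code an alignment: 1..4 for A,C,G,T; NA for gap/ambiguity.
code_alignment <- function(aln) {
  x <- match(aln$mat, BASES)
  dim(x) <- dim(aln$mat)
  rownames(x) <- aln$taxa
  x
}

# Columns usable under complete deletion (no NA anywhere).
complete_columns <- function(x) which(colSums(is.na(x)) == 0)

#' p-distance between two aligned sequences
#'
#' @param row_a,row_b Equal-length sequences, as strings or character vectors
#'   of single symbols.
#' @param deletion `"pairwise"` skips, for this pair, every column where
#'   either symbol is not a plain base; `"complete-context"` asserts the
#'   caller already removed such columns globally and compares every column.
#' @return A list with `p`, the proportion of differing sites, and `m`, the
#'   number of compared sites.
#' @examples
#' p_distance("ACGT", "ACGA")$p  # 0.25
#' @export
p_distance <- function(row_a, row_b, deletion = c("pairwise", "complete-context")) {
  deletion <- match.arg(deletion)
  a <- if (length(row_a) == 1 && nchar(row_a) > 1) strsplit(row_a, "")[[1]] else row_a
  b <- if (length(row_b) == 1 && nchar(row_b) > 1) strsplit(row_b, "")[[1]] else row_b
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  a <- match(toupper(a), BASES)
  b <- match(toupper(b), BASES)
  ok <- !is.na(a) & !is.na(b)
  if (deletion == "complete-context" && !all(ok)) {
    stop("complete-context deletion requires gap/ambiguity columns to have been removed")
  }
  m <- sum(ok)
  if (m == 0) stop("no comparable sites between the two sequences")
  list(p = sum(a[ok] != b[ok]) / m, m = m)
}

# Pair bookkeeping: indices of all i<j pairs of n taxa.
pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  cbind(i = i, j = j)
}

# Per-pair site profiles over a coded matrix: logical matrices (pairs x
# sites) of "both usable" and "both usable and different". Computed once,
# then every bootstrap replicate is a cheap column subset.
pair_profiles <- function(x) {
  n <- nrow(x)
  pi <- pair_index(n)
  valid <- matrix(FALSE, nrow(pi), ncol(x))
  diff <- matrix(FALSE, nrow(pi), ncol(x))
  for (k in seq_len(nrow(pi))) {
    a <- x[pi[k, 1], ]
    b <- x[pi[k, 2], ]
    v <- !is.na(a) & !is.na(b)
    valid[k, ] <- v
    diff[k, ] <- v & (a != b)
  }
  list(pairs = pi, valid = valid, diff = diff, taxa = rownames(x))
}

# Distance matrix for one column multiset `idx`. Returns NULL (a degenerate
# replicate) if some pair has no usable column under pairwise deletion.
profile_dist <- function(prof, idx, all_valid = FALSE) {
  nd <- rowSums(prof$diff[, idx, drop = FALSE])
  nv <- if (all_valid) length(idx) else rowSums(prof$valid[, idx, drop = FALSE])
  if (any(nv == 0)) return(NULL)
  n <- length(prof$taxa)
  d <- matrix(0, n, n, dimnames = list(prof$taxa, prof$taxa))
  d[prof$pairs] <- nd / nv
  d[prof$pairs[, c(2, 1), drop = FALSE]] <- nd / nv
  d
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln A `substab_aln` with at least 3 taxa.
#' @param deletion `"complete"` (default) removes every column containing a
#'   gap, `N` or ambiguity code in any row, once, before computing; all pairs
#'   then share the same columns. `"pairwise"` drops unusable columns per
#'   pair.
#' @return An object of class `substab_dist`: list with `taxa`, `d` (the
#'   symmetric p-distance matrix), `valid_sites` (per-pair compared-site
#'   counts), `deletion`, and `n_sites_used` (columns surviving complete
#'   deletion, or the alignment length under pairwise).
#' @export
distance_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "substab_aln"))
  if (length(aln$taxa) < 3) stop("distance matrix needs at least 3 taxa")
  x <- code_alignment(aln)
  if (deletion == "complete") {
    keep <- complete_columns(x)
    if (!length(keep)) {
      stop("complete deletion removed every column: no gap-free sites")
    }
    x <- x[, keep, drop = FALSE]
  }
  prof <- pair_profiles(x)
  nv <- rowSums(prof$valid)
  if (any(nv == 0)) {
    k <- which(nv == 0)[1]
    stop(sprintf("no comparable sites between taxa '%s' and '%s'",
                 prof$taxa[prof$pairs[k, 1]], prof$taxa[prof$pairs[k, 2]]))
  }
  d <- profile_dist(prof, seq_len(ncol(x)), all_valid = (deletion == "complete"))
  n <- length(aln$taxa)
  vs <- matrix(0L, n, n, dimnames = list(aln$taxa, aln$taxa))
  vs[prof$pairs] <- as.integer(nv)
  vs[prof$pairs[, c(2, 1), drop = FALSE]] <- as.integer(nv)
  structure(list(taxa = aln$taxa, d = d, valid_sites = vs,
                 deletion = deletion, n_sites_used = ncol(x)),
            class = "substab_dist")
}

#' @export
print.substab_dist <- function(x, ...) {
  cat(sprintf("p-distance matrix: %d taxa, %s deletion, %d sites used\n",
              length(x$taxa), x$deletion, x$n_sites_used))
  print(round(x$d, 4))
  invisible(x)
}

#' Export a distance matrix as TSV
#'
#' Writes a square tab-separated table with taxa as both header row and first
#' column, mainly for debugging and audit.
#'
#' @param dm A `substab_dist` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance <- function(dm, path) {
  stopifnot(inherits(dm, "substab_dist"))
  utils::write.table(dm$d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
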