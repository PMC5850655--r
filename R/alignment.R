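# Multiple sequence alignment container and I/O (FASTA, relaxed PHYLIP).

# Alphabet: the four bases, gap, and the IUPAC ambiguity codes. U is
# normalized to T on input; everything outside ACGT is treated as missing
# data by the distance module.
ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a validated alignment
#'
#' An alignment is stored as a character matrix of single uppercase symbols
#' with one row per taxon; row names are the taxon names. Sequences must be
#' equal-length, taxon names unique and nonempty, and every symbol must be a
#' base, a gap (`-`), `N`, or an IUPAC ambiguity code. `U` and lowercase
#' input are normalized.
#'
#' @param seqs Named character vector of sequence strings, or a character
#'   matrix of single symbols with row names.
#' @return An object of class `substab_aln`: a list with elements `taxa`
#'   (character), `mat` (character matrix, taxa x sites) and `n_sites`.
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "ACGA", c = "AC-T", d = "acgu"))
#' aln$n_sites
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
    taxa <- rownames(mat)
    if (is.null(taxa)) stop("sequence matrix must have row names (taxon names)")
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- taxa[which(lens != lens[1])[1]]
      stop(sprintf(
        "alignment rows have unequal lengths: taxon '%s' has %d sites, expected %d",
        bad, nchar(seqs[bad]), lens[1]))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- taxa
  }
  if (any(!nzchar(taxa))) stop("taxon names must be nonempty")
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon name: '%s'", taxa[duplicated(taxa)][1]))
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- which(!(mat %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    stop(sprintf(
      "unknown character '%s' at site %d of taxon '%s' (%d offending site%s in total)",
      mat[bad[1]], j, taxa[i], length(bad), if (length(bad) > 1) "s" else ""))
  }
  structure(list(taxa = rownames(mat), mat = mat, n_sites = ncol(mat)),
            class = "substab_aln")
}

#' @export
print.substab_aln <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa, %d sites\n", length(x$taxa), x$n_sites))
  shown <- utils::head(x$taxa, 6)
  for (t in shown) {
    s <- paste(x$mat[t, seq_len(min(40, x$n_sites))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (x$n_sites > 40) "..." else ""))
  }
  if (length(x$taxa) > 6) cat(sprintf("  ... and %d more\n", length(x$taxa) - 6))
  invisible(x)
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' `format = "auto"` sniffs the first non-blank character: `>` means FASTA,
#' anything else is parsed as PHYLIP (a `n_taxa n_sites` header followed by
#' whitespace-delimited name + sequence records; names may be up to 64
#' characters and sequences may continue over several lines).
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"phylip"`.
#' @return A `substab_aln` object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("alignment file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    if (is.na(first)) stop(sprintf("empty alignment file: '%s'", path))
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") parse_fasta(lines) else parse_phylip(lines)
}

# FASTA: the taxon name is the header up to the first whitespace.
parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records found")
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- character(length(hdr))
  names(seqs) <- vapply(lines[hdr], function(h) {
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1]
  }, "", USE.NAMES = FALSE)
  for (k in seq_along(hdr)) {
    body <- lines[seq(hdr[k] + 1, ends[k])]
    body <- body[!startsWith(body, ">")]
    seqs[k] <- gsub("\\s", "", paste(body, collapse = ""))
  }
  alignment(seqs)
}

# Relaxed sequential PHYLIP: header "n L"; then tokens alternating a taxon
# name and as many sequence chunks as needed to reach L sites.
parse_phylip <- function(lines) {
  toks <- unlist(strsplit(trimws(lines), "\\s+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2) stop("malformed PHYLIP header")
  n <- suppressWarnings(as.integer(toks[1]))
  L <- suppressWarnings(as.integer(toks[2]))
  if (is.na(n) || is.na(L)) stop("malformed PHYLIP header: expected 'n_taxa n_sites'")
  toks <- toks[-(1:2)]
  seqs <- character(n)
  nms <- character(n)
  i <- 1
  for (k in seq_len(n)) {
    if (i > length(toks)) stop(sprintf("PHYLIP file truncated before taxon %d", k))
    nms[k] <- toks[i]
    if (nchar(nms[k]) > 64) stop(sprintf("taxon name longer than 64 characters: '%s'", nms[k]))
    i <- i + 1
    s <- ""
    while (nchar(s) < L) {
      if (i > length(toks)) {
        stop(sprintf("sequence for taxon '%s' has %d sites, header promises %d",
                     nms[k], nchar(s), L))
      }
      s <- paste0(s, toks[i])
      i <- i + 1
    }
    if (nchar(s) != L) {
      stop(sprintf("sequence for taxon '%s' has %d sites, header promises %d",
                   nms[k], nchar(s), L))
    }
    seqs[k] <- s
  }
  names(seqs) <- nms
  alignment(seqs)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param aln A `substab_aln` object.
#' @param path Output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param width Line width for FASTA sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip"), width = 70) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "substab_aln"))
  rows <- apply(aln$mat, 1, paste, collapse = "")
  if (format == "fasta") {
    out <- unlist(lapply(aln$taxa, function(t) {
      s <- rows[[t]]
      chunks <- substring(s, seq(1, nchar(s), width),
                          pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
      c(paste0(">", t), chunks)
    }))
  } else {
    out <- c(sprintf("%d %d", length(aln$taxa), aln$n_sites),
             sprintf("%s  %s", aln$taxa, rows[aln$taxa]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Restrict an alignment to a subset of taxa
#'
#' Rows are returned in the requested order; sites are untouched. This is the
#' operation behind the subtree-stability test, which bootstraps only the
#' clade members plus one closest outgroup.
#'
#' @param aln A `substab_aln` object.
#' @param taxa Character vector of taxon names to keep, all present in `aln`.
#' @return A `substab_aln` on exactly `taxa`.
#' @export
restrict_alignment <- function(aln, taxa) {
  stopifnot(inherits(aln, "substab_aln"))
  missing <- setdiff(taxa, aln$taxa)
  if (length(missing)) {
    stop(sprintf("taxon not present in alignment: '%s'", missing[1]))
  }
  alignment(aln$mat[taxa, , drop = FALSE])
}
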