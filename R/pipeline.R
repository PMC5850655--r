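# File-writing pipeline: one call runs the whole analysis and writes the
# annotated Newick, the per-clade TSV table, a JSON audit with every
# per-outgroup (s, N, ps), and a plain-text run log. Outputs carry no
# timestamps, so a fixed (alignment, seed, replicates, flags) configuration
# produces byte-identical files.

#' Run the full analysis pipeline and write its reports
#'
#' @param config A list (or arguments captured as one) with elements:
#'   `alignment` (path or `substab_aln`), `format`, `replicates`, `seed`,
#'   `deletion`, `root_outgroup`, `identity_bootstrap`, `dump_replicates`,
#'   and `out_prefix` (required: output files are `<prefix>.nwk`,
#'   `<prefix>.tsv`, `<prefix>.json`, `<prefix>.log`).
#' @return The fitted `substab` object, invisibly, with attribute `"files"`
#'   naming the written outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$alignment), !is.null(config$out_prefix))
  warnings_seen <- character(0)
  messages_seen <- character(0)
  fit <- withCallingHandlers(
    substab(config$alignment,
            replicates = config$replicates %||% 1000,
            seed = config$seed %||% 1,
            deletion = config$deletion %||% "complete",
            root_outgroup = config$root_outgroup,
            identity_bootstrap = isTRUE(config$identity_bootstrap),
            format = config$format %||% "auto"),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages_seen <<- c(messages_seen, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  prefix <- config$out_prefix
  files <- c(newick = paste0(prefix, ".nwk"),
             table = paste0(prefix, ".tsv"),
             audit = paste0(prefix, ".json"),
             log = paste0(prefix, ".log"))

  writeLines(write_newick(annotated_tree(fit)), files[["newick"]])

  tab <- fit$clade_table
  tab$ps_mean <- ifelse(is.na(tab$ps_mean), "NA",
                        format(round(tab$ps_mean, 4), trim = TRUE, scientific = FALSE))
  utils::write.table(tab[, c("clade", "size", "pb", "n_outgroups", "outgroups",
                             "ps_values", "s_over_N", "ps_mean", "ps_reason")],
                     files[["table"]], sep = "\t", quote = FALSE, row.names = FALSE)

  audit <- list(
    meta = fit$meta,
    tree = write_newick(fit$tree),
    branches = fit$pb[, c("clade", "size", "pb", "replicates")],
    clades = lapply(fit$stability, function(s) {
      list(clade = s$clade_taxa,
           sister = s$sister_taxa,
           per_outgroup = s$per_outgroup,
           ps_mean = s$ps_mean,
           reason = s$reason %||% NULL)
    })
  )
  jsonlite::write_json(audit, files[["audit"]], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  log_lines <- c(
    sprintf("substab %s", fit$meta$version),
    sprintf("alignment: %d taxa, %d sites (%d used, %s deletion)",
            fit$meta$n_taxa, fit$meta$n_sites, fit$meta$n_sites_used,
            fit$meta$deletion),
    sprintf("replicates: %d  seed: %d", fit$meta$replicates, fit$meta$seed),
    sprintf("root outgroup: %s (%s)", fit$meta$root_outgroup, fit$meta$rooting),
    sprintf("degenerate replicates: Pb %d, Ps %d",
            fit$meta$failed_pb_replicates, fit$meta$failed_ps_replicates),
    if (length(messages_seen)) paste("note:", messages_seen) else character(0),
    if (length(warnings_seen)) paste("warning:", warnings_seen) else character(0)
  )
  writeLines(log_lines, files[["log"]])

  if (isTRUE(config$dump_replicates)) {
    dump_replicate_trees(fit, paste0(prefix, ".boot.nwk"))
    files <- c(files, replicates = paste0(prefix, ".boot.nwk"))
  }

  attr(fit, "files") <- files
  invisible(fit)
}

# Re-derive and write the full-tree bootstrap replicate trees (audit aid;
# the replicate stream is a pure function of the seed, so this reproduces
# exactly the trees that were scored).
dump_replicate_trees <- function(fit, path) {
  aln <- fit$alignment
  m <- fit$meta
  x <- prepare_coded(aln, m$deletion)
  prof <- pair_profiles(x)
  trees <- vector("list", m$replicates)
  i <- 0L
  bootstrap_replicates(prof, m$replicates, m$seed, key = "pb",
                       identity_bootstrap = m$identity_bootstrap,
                       all_valid = (m$deletion == "complete"),
                       score = function(tr) {
                         i <<- i + 1L
                         trees[[i]] <<- tr
                       })
  txt <- vapply(trees, function(tr) if (is.null(tr)) "" else write_newick(tr), "")
  writeLines(txt[nzchar(txt)], path)
  invisible(path)
}
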