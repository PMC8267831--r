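# Tabular/file exports for the pipeline's external interfaces: metric
# records, cluster tables, alignments with partitions, phyly reports and a
# human-readable summary.

#' Pairwise metric records
#'
#' One row per unordered pair: ANI, AAI, dDDH, CP1-3, PD, 16S identity and
#' the two G+C contents.  Values are computed on demand through the
#' context's caches.
#'
#' @param ctx an `analysis_context`.
#' @param pairs two-column character matrix of strain ids.
#' @return data.frame in the metric-matrix TSV layout.
#' @export
metric_table <- function(ctx, pairs) {
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ad <- ctx_ani_dddh(ctx, a, b)
    cp <- ctx_cp(ctx, a, b)
    data.frame(strain_a = a, strain_b = b,
               ani = ad$ani, aai = ctx_aai(ctx, a, b), dddh = ad$dddh,
               cp1 = cp[["cp1"]], cp2 = cp[["cp2"]], cp3 = cp[["cp3"]],
               pd = ctx_pd(ctx, a, b),
               s16_identity = suppressWarnings(
                 s16_identity(ctx$records[[a]], ctx$records[[b]])),
               gc_a = gc_content(ctx$records[[a]]),
               gc_b = gc_content(ctx$records[[b]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the core-genome artifacts of a context
#'
#' Cluster table TSV, concatenated protein and nucleotide alignments as
#' multi-FASTA, and the per-gene partition table.
#'
#' @param ctx an `analysis_context`.
#' @param dir output directory.
#' @export
write_core_artifacts <- function(ctx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl_tab <- do.call(rbind, lapply(ctx$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, centroid = cl$centroid,
               is_core = cl$is_core,
               strain_id = cl$members$strain_id,
               gene_id = cl$members$gene_id, stringsAsFactors = FALSE)
  }))
  write.table(cl_tab, file.path(dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  al <- ctx$alignment
  mat_to_fasta <- function(M) {
    setNames(apply(M, 1, function(row) intToUtf8(row)), rownames(M))
  }
  write_fasta_chr(mat_to_fasta(al$aa),
                  file.path(dir, "core_alignment_protein.faa"), "aa")
  writeLines(paste0(">", al$strains, "\n",
                    apply(al$nt, 1, intToUtf8)[al$strains]),
             file.path(dir, "core_alignment_nt.fna"))
  write.table(al$blocks, file.path(dir, "partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Phyly report table
#'
#' @param ctx an `analysis_context`.
#' @return data.frame: genus, status, sizes, intruders and pure-clade
#'   decomposition.
#' @export
phyly_table <- function(ctx) {
  do.call(rbind, lapply(names(ctx$phyly), function(g) {
    r <- ctx$phyly[[g]]
    data.frame(genus = g, status = r$status, n_tips = length(r$group),
               n_intruders = length(r$intruders),
               n_pure_clades = length(r$pure_clades),
               intruders = paste(sort(r$intruders), collapse = ";"),
               pure_clades = paste(vapply(r$pure_clades, function(tp)
                 paste(sort(tp), collapse = ","), character(1)),
                 collapse = " | "),
               stringsAsFactors = FALSE)
  }))
}

#' Human-readable revision summary (markdown)
#'
#' @param result output of [revise_taxonomy()].
#' @return character vector of markdown lines.
#' @export
revision_report <- function(result) {
  ctx <- result$context
  st <- table(vapply(ctx$phyly, function(r) r$status, character(1)))
  lines <- c(
    "# Taxonomic revision summary", "",
    sprintf("* strains analysed: %d", length(ctx$records)),
    sprintf("* core genes: %d (%d aligned aa positions)",
            nrow(ctx$alignment$blocks), ncol(ctx$alignment$aa)),
    sprintf("* genera: %s",
            paste(names(st), as.integer(st), collapse = ", ")),
    "", "## Proposals", "")
  pr <- result$proposals
  if (!nrow(pr)) {
    lines <- c(lines, "No reclassification proposals.")
  } else {
    for (r in seq_len(nrow(pr))) {
      lines <- c(lines, sprintf(
        "* **%s** — %s -> %s (%d name change%s); evidence: %s",
        pr$action[r], pr$subjects[r],
        ifelse(is.na(pr$destination[r]), "-", pr$destination[r]),
        pr$name_changes[r], ifelse(pr$name_changes[r] == 1, "", "s"),
        pr$evidence[r]))
    }
  }
  if (!is.null(result$family_tests)) {
    ps <- vapply(result$family_tests, function(t) t$p.value, numeric(1))
    lines <- c(lines, "", "## Family-level tests", "",
               paste0("* ", names(ps), ": p = ", format_p(ps)))
  }
  lines
}
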