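# Core-genome identification: greedy centroid clustering of protein
# sequences, per-cluster progressive alignment with codon-aware
# back-translation, and concatenation into the matrices that feed the
# phylogeny and the codon-position similarities.

#' Greedy centroid clustering of annotated genes
#'
#' Sequences are sorted by decreasing protein length (ties broken
#' lexicographically by strain_id then gene_id); each sequence joins the
#' first existing centroid whose global-alignment protein identity meets
#' `identity_threshold`, otherwise it founds a new cluster.  Deterministic
#' given the input and the tie rule.
#'
#' @param records named list of strain records.
#' @param identity_threshold fraction in (0, 1].
#' @return list of gene clusters; each has `cluster_id`, `centroid`,
#'   `members` (data.frame strain_id, gene_id, protein_seq, nucleotide_seq,
#'   codon_ok) and `is_core` (single-copy in every strain).
#' @export
cluster_genes <- function(records, identity_threshold = 0.5) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]")
  }
  pool <- do.call(rbind, lapply(records, function(r) {
    g <- r$genes[!is.na(r$genes$protein_seq), , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(strain_id = r$strain_id, gene_id = g$gene_id,
               protein_seq = g$protein_seq, nucleotide_seq = g$nucleotide_seq,
               codon_ok = g$codon_ok, stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || !nrow(pool)) stop("no protein sequences to cluster")
  ord <- order(-nchar(pool$protein_seq), pool$strain_id, pool$gene_id)
  pool <- pool[ord, , drop = FALSE]
  n <- nrow(pool)
  kmers <- lapply(pool$protein_seq, kmer_set, k = 3)
  ints <- lapply(pool$protein_seq, seq_to_int)
  assignment <- integer(n)
  centroid_idx <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(centroid_idx)) {
      j <- centroid_idx[ci]
      # equal-length fast path: the ungapped identity decides directly
      if (length(ints[[i]]) == length(ints[[j]])) {
        h <- cpp_hamming_identity(ints[[i]], ints[[j]])
        if (h >= identity_threshold) { hit <- ci; break }
        if (h < identity_threshold - 0.1) next
      }
      # 3-mer prefilter: shared-3-mer count must clearly exceed the random
      # background (~ la*lb/20^3) before paying for dynamic programming
      shared <- sum(kmers[[i]] %in% kmers[[j]])
      bg <- length(kmers[[i]]) * length(kmers[[j]]) / 8000
      if (shared < bg + 5 * sqrt(bg) + 1) next
      idn <- pair_identity(pool$protein_seq[i], pool$protein_seq[j],
                           type = "protein")
      if (!is.na(idn) && idn >= identity_threshold) { hit <- ci; break }
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, i)
      hit <- length(centroid_idx)
    }
    assignment[i] <- hit
  }
  all_strains <- names(records)
  lapply(seq_along(centroid_idx), function(ci) {
    members <- pool[assignment == ci, , drop = FALSE]
    rownames(members) <- NULL
    tab <- table(members$strain_id)
    is_core <- setequal(names(tab), all_strains) && all(tab == 1L)
    structure(list(cluster_id = sprintf("c%03d", ci),
                   centroid = members$gene_id[1], members = members,
                   is_core = is_core),
              class = "gene_cluster")
  })
}

#' Align one core gene cluster
#'
#' Progressive protein alignment ([align_sequences()]); the nucleotide block
#' replaces each aligned residue with its source codon and each gap with
#' three gap symbols.
#'
#' @param cluster a core cluster from [cluster_genes()].
#' @return list with `aa` and `nt` integer-coded alignment matrices (rows
#'   named by strain), and `gene_ids`.
#' @export
align_cluster <- function(cluster) {
  if (!isTRUE(cluster$is_core)) {
    stop("align_cluster expects a core (single-copy, all-strain) cluster")
  }
  m <- cluster$members
  bad <- !m$codon_ok
  if (any(bad)) {
    warning("cluster ", cluster$cluster_id,
            ": excluding gene(s) with CDS/protein length mismatch: ",
            paste(m$gene_id[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  if (!nrow(m)) stop("cluster ", cluster$cluster_id, " has no usable genes")
  aa <- align_sequences(setNames(m$protein_seq, m$strain_id), "protein")
  L <- ncol(aa)
  nt <- matrix(GAP_CODE, nrow(aa), 3L * L, dimnames = list(rownames(aa),
                                                           NULL))
  for (i in seq_len(nrow(aa))) {
    codons <- seq_to_int(m$nucleotide_seq[m$strain_id == rownames(aa)[i]])
    res_cols <- which(aa[i, ] != GAP_CODE)
    src <- rep((seq_along(res_cols) - 1L) * 3L, each = 3L) + 1:3
    dst <- rep((res_cols - 1L) * 3L, each = 3L) + 1:3
    nt[i, dst] <- codons[src]
  }
  list(aa = aa, nt = nt, gene_ids = setNames(m$gene_id, m$strain_id),
       cluster_id = cluster$cluster_id)
}

#' Concatenate aligned gene blocks
#'
#' @param blocks list of aligned blocks from [align_cluster()]; all must
#'   cover the identical strain set.
#' @param strain_order optional row order for the result.
#' @return a `concat_alignment`: integer-coded `aa` and `nt` matrices, the
#'   strain order, and per-block column ranges for partition-aware analyses.
#' @export
concatenate <- function(blocks, strain_order = NULL) {
  if (!length(blocks)) stop("empty block list")
  strains <- sort(rownames(blocks[[1]]$aa))
  for (b in blocks) {
    if (!setequal(rownames(b$aa), strains)) {
      stop("strain sets differ across blocks (", b$cluster_id, ")")
    }
  }
  if (is.null(strain_order)) strain_order <- strains
  stopifnot(setequal(strain_order, strains))
  aa <- do.call(cbind, lapply(blocks, function(b) {
    b$aa[strain_order, , drop = FALSE]
  }))
  nt <- do.call(cbind, lapply(blocks, function(b) {
    b$nt[strain_order, , drop = FALSE]
  }))
  aa_len <- vapply(blocks, function(b) ncol(b$aa), integer(1))
  ends <- cumsum(aa_len)
  parts <- data.frame(
    block = vapply(blocks, function(b) b$cluster_id, character(1)),
    aa_start = c(1L, head(ends, -1) + 1L), aa_end = ends,
    stringsAsFactors = FALSE)
  parts$nt_start <- (parts$aa_start - 1L) * 3L + 1L
  parts$nt_end <- parts$aa_end * 3L
  structure(list(aa = aa, nt = nt, strains = strain_order, blocks = parts),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat("<concat_alignment>", length(x$strains), "strains,",
      nrow(x$blocks), "gene blocks,", ncol(x$aa), "aa /", ncol(x$nt),
      "nt columns\n")
  invisible(x)
}

#' Identify, align and concatenate the core genome
#'
#' Convenience wrapper: clusters genes, keeps single-copy all-strain clusters
#' whose members all pass the codon sanity check, aligns and concatenates.
#'
#' @param records named list of strain records.
#' @param identity_threshold clustering identity threshold.
#' @return list with `alignment` (a `concat_alignment`) and `clusters` (all
#'   clusters, core or not).
#' @export
build_core_alignment <- function(records, identity_threshold = 0.5) {
  clusters <- cluster_genes(records, identity_threshold)
  core <- Filter(function(cl) cl$is_core && all(cl$members$codon_ok),
                 clusters)
  if (!length(core)) stop("no core gene clusters found")
  blocks <- lapply(core, align_cluster)
  list(alignment = concatenate(blocks), clusters = clusters)
}
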