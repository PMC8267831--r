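# Pairwise genomic similarity metrics.  The published analyses used external
# engines as black boxes (fragment-based ANI, genome-to-genome distance dDDH,
# reciprocal-best-hit AAI); this module re-implements the algorithmic cores
# with the fragment/filter constants exposed in the thresholds list.  The
# fragment matcher is k-mer seeded with positional (ungapped) extension,
# which is exact for the indel-free genomes the generator produces and a
# close stand-in for banded extension on real genomes.

#' G+C content of a genome
#'
#' 100 * (G+C) / (A+C+G+T) over all non-plasmid sequences; ambiguity codes
#' are excluded from numerator and denominator.
#' @param record a [strain_record()].
#' @export
gc_content <- function(record) {
  seqs <- record$genome[!record$plasmid]
  if (!length(seqs) || !any(nchar(seqs) > 0)) stop("empty genome")
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, c("A", "C", "G", "T"), drop = FALSE])
  100 * (counts[["G"]] + counts[["C"]]) / sum(counts)
}

genome_string <- function(record) {
  paste(record$genome[!record$plasmid], collapse = "")
}

# per-strain caches (genome kmer tables, protein codes) live in an
# environment so repeated pairwise calls stay cheap
new_metric_cache <- function() new.env(parent = emptyenv())

cache_get <- function(cache, key, make) {
  if (is.null(cache)) return(make())
  if (is.null(cache[[key]])) cache[[key]] <- make()
  cache[[key]]
}

genome_ints <- function(record, cache = NULL) {
  cache_get(cache, paste0("gi_", record$strain_id),
            function() seq_to_int(genome_string(record)))
}

genome_kmers <- function(record, k, cache = NULL) {
  cache_get(cache, paste0("gk_", record$strain_id), function() {
    s <- genome_string(record)
    n <- nchar(s)
    if (n < k) character() else substring(s, 1:(n - k + 1L), k:n)
  })
}

# match one fragment (int vector) against the subject at its modal k-mer
# diagonal, then trim to the best-scoring contiguous segment (+1 match /
# -1 mismatch), mimicking local-alignment extension: windows straddling a
# gene-content difference keep only their homologous part and fail the
# coverage filter instead of contributing a half-random identity.
match_fragment <- function(frag, probe_pos, probe_hits, subj_int) {
  ok <- !is.na(probe_hits)
  if (!any(ok)) return(NULL)
  starts <- probe_hits[ok] - probe_pos[ok] + 1L
  tab <- table(starts)
  start <- as.integer(names(tab)[which.max(tab)])
  L <- length(frag)
  s1 <- max(start, 1L)
  s2 <- min(start + L - 1L, length(subj_int))
  if (s2 < s1) return(NULL)
  q1 <- s1 - start + 1L
  q2 <- q1 + (s2 - s1)
  m <- frag[q1:q2] == subj_int[s1:s2]
  # max-scoring subsegment via prefix sums
  pref <- cumsum(2 * m - 1)
  runmin <- cummin(c(0, pref[-length(pref)]))
  gains <- pref - runmin
  j <- which.max(gains)
  i <- which(c(0, pref[-length(pref)]) == runmin[j])
  i <- i[i <= j][1]
  seg <- m[i:j]
  c(identity = mean(seg), coverage = length(seg) / L, len = length(seg))
}

ani_one_direction <- function(query, subject, thresholds, cache,
                              k = 12L, probe_step = 3L) {
  qi <- genome_ints(query, cache)
  si <- genome_ints(subject, cache)
  sk <- genome_kmers(subject, k, cache)
  f <- thresholds$fragment_length
  n_frag <- length(qi) %/% f
  if (n_frag == 0L || !length(sk)) {
    return(list(idents = numeric(), wsum = 0, lsum = 0))
  }
  qs <- genome_string(query)
  probe_pos <- seq.int(1L, f - k + 1L, by = probe_step)
  idents <- numeric(0)
  wsum <- 0; lsum <- 0
  # look up all probes of all fragments in one match() call
  all_pos <- as.vector(outer(probe_pos, (seq_len(n_frag) - 1L) * f, "+"))
  probes <- substring(qs, all_pos, all_pos + k - 1L)
  hits <- match(probes, sk)
  np <- length(probe_pos)
  for (fr in seq_len(n_frag)) {
    fs <- (fr - 1L) * f + 1L
    frag <- qi[fs:(fs + f - 1L)]
    h <- hits[((fr - 1L) * np + 1L):(fr * np)]
    m <- match_fragment(frag, probe_pos, h, si)
    if (is.null(m)) next
    if (100 * m[["identity"]] > thresholds$ani_min_identity &&
        100 * m[["coverage"]] > thresholds$ani_min_coverage) {
      idents <- c(idents, m[["identity"]])
      wsum <- wsum + m[["identity"]] * m[["len"]]
      lsum <- lsum + m[["len"]]
    }
  }
  list(idents = idents, wsum = wsum, lsum = lsum)
}

#' Average nucleotide identity and digital DDH of a genome pair
#'
#' The query genome is cut into fixed-length fragments; each fragment is
#' placed on the subject at its modal k-mer diagonal and scored ungapped.
#' Fragments are retained when identity exceeds `ani_min_identity` and
#' coverage `ani_min_coverage`; ANI is the mean retained-fragment identity,
#' averaged over the two reciprocal directions.  dDDH is derived from the
#' same matched segments: intergenomic distance d = 1 - sum(identities x
#' length)/sum(length), mapped through the monotone calibration
#' dDDH = 100 exp(-dddh_rate d) (so identical genomes give exactly 100, and
#' the 95 ANI / 70 dDDH species boundaries coincide).
#'
#' @param a,b strain records.
#' @param thresholds a [default_thresholds()] list.
#' @param cache optional environment from [new_metric_cache()].
#' @return list with `ani` and `dddh` (percent; NA when no fragments are
#'   retained).
#' @export
ani_dddh <- function(a, b, thresholds = default_thresholds(), cache = NULL) {
  if (!nchar(genome_string(a)) || !nchar(genome_string(b))) {
    stop("empty genome")
  }
  d1 <- ani_one_direction(a, b, thresholds, cache)
  d2 <- ani_one_direction(b, a, thresholds, cache)
  means <- c(if (length(d1$idents)) mean(d1$idents),
             if (length(d2$idents)) mean(d2$idents))
  if (!length(means)) {
    warning("no retained fragments for ", a$strain_id, " / ", b$strain_id)
    return(list(ani = NA_real_, dddh = NA_real_))
  }
  ani <- 100 * mean(means)
  dist <- 1 - (d1$wsum + d2$wsum) / (d1$lsum + d2$lsum)
  list(ani = ani, dddh = 100 * exp(-thresholds$dddh_rate * dist))
}

#' @rdname ani_dddh
#' @export
ani <- function(a, b, thresholds = default_thresholds(), cache = NULL) {
  ani_dddh(a, b, thresholds, cache)$ani
}

#' @rdname ani_dddh
#' @export
ddd_hybridization <- function(a, b, thresholds = default_thresholds(),
                              cache = NULL) {
  ani_dddh(a, b, thresholds, cache)$dddh
}

proteome_of <- function(record, cache = NULL) {
  cache_get(cache, paste0("pr_", record$strain_id), function() {
    g <- record$genes[!is.na(record$genes$protein_seq), , drop = FALSE]
    B <- blosum62()
    # character-code -> BLOSUM row index, for fast integer-indexed scoring
    code_map <- rep(match("X", rownames(B)), 128L)
    code_map[vapply(rownames(B), utf8ToInt, integer(1))] <-
      seq_len(nrow(B))
    # sparse protein x 3-mer incidence over the 20^3 k-mer universe, for
    # one-shot candidate search via a crossproduct
    aa_map <- rep(NA_integer_, 128L)
    aa_map[vapply(AA20, utf8ToInt, integer(1))] <- 0:19
    km <- lapply(g$protein_seq, function(s) {
      v <- aa_map[seq_to_int(s)]
      v[is.na(v)] <- 0L
      L <- length(v)
      if (L < 3L) return(integer())
      unique((v[1:(L - 2)] * 20L + v[2:(L - 1)]) * 20L + v[3:L] + 1L)
    })
    inc <- Matrix::sparseMatrix(
      i = rep(seq_along(km), lengths(km)), j = unlist(km), x = 1,
      dims = c(nrow(g), 8000L))
    list(seqs = g$protein_seq,
         ints = lapply(g$protein_seq, seq_to_int),
         bidx = lapply(g$protein_seq, function(s) code_map[seq_to_int(s)]),
         inc = inc, n = nrow(g))
  })
}

# score/identity/coverage of protein i of P against protein j of Q
score_pair <- function(i, j, P, Q) {
  a <- P$seqs[[i]]; b <- Q$seqs[[j]]
  if (nchar(a) == nchar(b)) {
    B <- blosum62()
    c(score = sum(B[cbind(P$bidx[[i]], Q$bidx[[j]])]),
      identity = cpp_hamming_identity(P$ints[[i]], Q$ints[[j]]),
      coverage = 1)
  } else {
    al <- pairwise_align(a, b, "protein")
    both <- sum(al$a != GAP_CODE & al$b != GAP_CODE)
    c(score = al$score, identity = aligned_identity(al$a, al$b),
      coverage = both / min(nchar(a), nchar(b)))
  }
}

# best hit of protein i of P in Q given the k-mer overlap row ov (length
# Q$n): alignment score over the top candidates whose shared-3-mer count
# clearly exceeds the random background; NULL when none does
best_hit <- function(i, P, Q, ov, n_cand = 3L) {
  cand <- order(ov, decreasing = TRUE)[seq_len(min(n_cand, Q$n))]
  li <- nchar(P$seqs[[i]]) - 2L
  bg <- li * (vapply(Q$seqs[cand], nchar, numeric(1)) - 2L) / 8000
  cand <- cand[ov[cand] > bg + 5 * sqrt(bg) + 1]
  if (!length(cand)) return(NULL)
  best <- NULL
  for (j in cand) {
    sc <- score_pair(i, j, P, Q)
    if (is.null(best) || sc[["score"]] > best[["score"]]) {
      best <- c(hit = j, sc)
    }
  }
  best
}

#' Average amino-acid identity of a proteome pair
#'
#' Reciprocal best hits by global protein alignment score; AAI is the mean
#' alignment identity over RBH pairs, discarding pairs below
#' `aai_min_identity` percent identity or `aai_min_coverage` percent
#' coverage of the shorter sequence.
#'
#' @inheritParams ani_dddh
#' @return AAI in percent, or NA when there are no reciprocal best hits.
#' @export
aai <- function(a, b, thresholds = default_thresholds(), cache = NULL) {
  P <- proteome_of(a, cache)
  Q <- proteome_of(b, cache)
  if (!P$n || !Q$n) stop("empty proteome")
  OV <- as.matrix(Matrix::tcrossprod(P$inc, Q$inc))
  fwd <- lapply(seq_len(P$n), function(i) best_hit(i, P, Q, OV[i, ]))
  back_memo <- vector("list", Q$n)
  idents <- numeric(0)
  for (i in seq_len(P$n)) {
    if (is.null(fwd[[i]])) next
    j <- as.integer(fwd[[i]][["hit"]])
    if (is.null(back_memo[[j]])) {
      back_memo[[j]] <- list(best_hit(j, Q, P, OV[, j]))
    }
    back <- back_memo[[j]][[1]]
    if (is.null(back) || as.integer(back[["hit"]]) != i) next
    idn <- fwd[[i]][["identity"]]
    cov <- fwd[[i]][["coverage"]]
    if (100 * idn <= thresholds$aai_min_identity ||
        100 * cov <= thresholds$aai_min_coverage) next
    idents <- c(idents, idn)
  }
  if (!length(idents)) return(NA_real_)
  100 * mean(idents)
}

#' Codon-position similarities of a strain pair
#'
#' Percent identity over the codon-aware nucleotide alignment at codon
#' positions 1-3; both-gap columns excluded.
#'
#' @param alignment a `concat_alignment`.
#' @param a,b strain ids (rows of the alignment).
#' @return named vector c(cp1, cp2, cp3).
#' @export
codon_position_similarity <- function(alignment, a, b) {
  M <- alignment$nt[c(a, b), , drop = FALSE]
  if (!ncol(M)) stop("no codon-aware columns")
  out <- vapply(1:3, function(k) {
    cols <- seq.int(k, ncol(M), by = 3L)
    D <- cpp_mismatch_dist(M[, cols, drop = FALSE], rep(1, length(cols)),
                           GAP_CODE)
    100 * (1 - D[1, 2])
  }, numeric(1))
  names(out) <- c("cp1", "cp2", "cp3")
  out
}

# all-pairs CP similarity matrices (cp1..cp3), percent
cp_similarity_matrices <- function(alignment) {
  lapply(setNames(1:3, c("cp1", "cp2", "cp3")), function(k) {
    cols <- seq.int(k, ncol(alignment$nt), by = 3L)
    D <- cpp_mismatch_dist(alignment$nt[, cols, drop = FALSE],
                           rep(1, length(cols)), GAP_CODE)
    dimnames(D) <- list(alignment$strains, alignment$strains)
    100 * (1 - D)
  })
}

#' 16S identity of a strain pair
#'
#' Global alignment identity of the two 16S marker genes.
#' @param a,b strain records.
#' @return percent identity, or NA (with a warning) when either strain lacks
#'   a 16S gene.
#' @export
s16_identity <- function(a, b) {
  get16 <- function(r) {
    s <- r$genes$nucleotide_seq[r$genes$marker_label == "16S"]
    if (!length(s)) NA_character_ else s[1]
  }
  sa <- get16(a); sb <- get16(b)
  if (is.na(sa) || is.na(sb)) {
    warning("missing 16S gene for ",
            paste(c(a$strain_id, b$strain_id)[c(is.na(sa), is.na(sb))],
                  collapse = ", "))
    return(NA_real_)
  }
  100 * pair_identity(sa, sb, type = "dna")
}
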