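# Sequence/alignment primitives shared by core_genome and metrics.
#
# Sequences are handled internally as integer vectors of character codes
# (utf8), with GAP_CODE for '-'.  The identity definition used throughout the
# package: matches / aligned columns, excluding columns gapped in both
# sequences and excluding terminal gap runs of either sequence.

GAP_CODE <- 45L # utf8ToInt("-")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

.tr_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.tr_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tr_cache$blosum62 <- e$BLOSUM62
  }
  .tr_cache$blosum62
}

dna_score_matrix <- function(match = 5, mismatch = -4) {
  letters <- IUPAC_NT
  S <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(S) <- match
  # ambiguity codes are conservatively treated as mismatches, even to
  # themselves, except the unambiguous self-matches above; N never matches.
  amb <- setdiff(letters, c("A", "C", "G", "T"))
  S[amb, amb] <- mismatch
  S
}

seq_to_int <- function(s) utf8ToInt(s)
int_to_seq <- function(x) intToUtf8(x)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# map unknown protein characters to X so BLOSUM lookup never fails
protein_chars <- function(s) {
  ch <- seq_chars(s)
  B <- blosum62()
  ch[!ch %in% rownames(B)] <- "X"
  ch
}

#' Identity of two aligned sequences
#'
#' Matches divided by aligned columns; columns gapped in both sequences and
#' terminal gap runs of either sequence are excluded.  This single identity
#' definition is used by the gene clusterer, the distance matrices and all
#' pairwise metrics.
#'
#' @param a,b aligned sequences of equal length (strings with `-` gaps, or
#'   integer code vectors).
#' @return identity as a fraction in \[0, 1\], or NA if no columns remain.
#' @export
aligned_identity <- function(a, b) {
  if (is.character(a)) a <- seq_to_int(a)
  if (is.character(b)) b <- seq_to_int(b)
  stopifnot(length(a) == length(b))
  L <- length(a)
  if (L == 0L) return(NA_real_)
  keep <- rep(TRUE, L)
  for (v in list(a, b)) {
    gaps <- v == GAP_CODE
    if (gaps[1]) keep[seq_len(which.min(gaps) - 1L)] <- FALSE
    if (gaps[L]) keep[seq.int(L - which.min(rev(gaps)) + 2L, L)] <- FALSE
  }
  keep <- keep & !(a == GAP_CODE & b == GAP_CODE)
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  sum(a[keep] == b[keep] & a[keep] != GAP_CODE) / n
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gap costs (BLOSUM62 for proteins, +5/-4 for
#' nucleotides).
#'
#' @param a,b unaligned sequences (strings).
#' @param type `"protein"` or `"dna"`.
#' @param gap_open,gap_ext affine gap penalties.
#' @return list with aligned integer-code vectors `a`, `b` and the `score`.
#' @export
pairwise_align <- function(a, b, type = c("protein", "dna"),
                           gap_open = 10, gap_ext = 0.5) {
  type <- match.arg(type)
  if (type == "protein") {
    B <- blosum62()
    ca <- protein_chars(a); cb <- protein_chars(b)
    S <- B[ca, cb, drop = FALSE]
  } else {
    B <- dna_score_matrix()
    ca <- seq_chars(a); cb <- seq_chars(b)
    S <- B[ca, cb, drop = FALSE]
  }
  res <- cpp_affine_align(S, gap_open, gap_ext)
  ai <- seq_to_int(a); bi <- seq_to_int(b)
  list(a = ifelse(res$idx1 == 0L, GAP_CODE, ai[pmax(res$idx1, 1L)]),
       b = ifelse(res$idx2 == 0L, GAP_CODE, bi[pmax(res$idx2, 1L)]),
       score = res$score)
}

# Identity of two unaligned sequences.  Fast path: equal-length pairs whose
# ungapped (Hamming) identity already clears `fast_min` are accepted without
# dynamic programming - at such identities the optimal global alignment of
# indel-free sequences is the ungapped one.
pair_identity <- function(a, b, type = "protein", fast_min = 0.4) {
  if (nchar(a) == nchar(b)) {
    h <- cpp_hamming_identity(seq_to_int(a), seq_to_int(b))
    if (!is.na(h) && h >= fast_min) return(h)
  }
  al <- pairwise_align(a, b, type)
  aligned_identity(al$a, al$b)
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

kmer_jaccard <- function(ka, kb) {
  if (!length(ka) || !length(kb)) return(0)
  inter <- sum(ka %in% kb)
  inter / (length(ka) + length(kb) - inter)
}

# ---- progressive multiple alignment ----------------------------------------

profile_freq <- function(M, codes) {
  # M: n x L integer matrix; returns L x |codes| frequency matrix over
  # non-gap entries of each column
  L <- ncol(M)
  FM <- vapply(codes, function(cd) colSums(M == cd), numeric(L))
  nong <- colSums(M != GAP_CODE)
  nong[nong == 0] <- 1
  FM / nong
}

merge_profiles <- function(M1, M2, SM, codes, gap_open, gap_ext) {
  F1 <- profile_freq(M1, codes)
  F2 <- profile_freq(M2, codes)
  S <- (F1 %*% SM) %*% t(F2)
  res <- cpp_affine_align(S, gap_open, gap_ext)
  K <- length(res$idx1)
  out <- matrix(GAP_CODE, nrow(M1) + nrow(M2), K)
  sel1 <- res$idx1 > 0L
  out[seq_len(nrow(M1)), sel1] <- M1[, res$idx1[sel1], drop = FALSE]
  sel2 <- res$idx2 > 0L
  out[nrow(M1) + seq_len(nrow(M2)), sel2] <- M2[, res$idx2[sel2], drop = FALSE]
  rownames(out) <- c(rownames(M1), rownames(M2))
  out
}

#' Progressive multiple alignment
#'
#' Guide tree by UPGMA on k-mer Jaccard distances, then profile-profile
#' merges with affine gap costs.  This is the in-package stand-in for an
#' external multiple aligner; the contract is the returned alignment, not the
#' engine.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param type `"protein"` or `"dna"`.
#' @param gap_open,gap_ext affine gap penalties.
#' @param k k-mer size for the guide-tree distance.
#' @return integer-coded alignment matrix, rows named as `seqs`.
#' @export
align_sequences <- function(seqs, type = c("protein", "dna"),
                            gap_open = 10, gap_ext = 0.5, k = 3) {
  type <- match.arg(type)
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (type == "protein") {
    SM0 <- blosum62()
    codes_chr <- AA20
  } else {
    SM0 <- dna_score_matrix()
    codes_chr <- c("A", "C", "G", "T")
  }
  SM <- SM0[codes_chr, codes_chr]
  codes <- vapply(codes_chr, utf8ToInt, integer(1))
  mats <- lapply(seq_along(seqs), function(i) {
    m <- matrix(seq_to_int(seqs[[i]]), nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  n <- length(seqs)
  if (n == 1L) return(mats[[1]])
  # indel-free fast path: equal-length, clearly homologous sequences align
  # ungapped (gap costs exceed any realignment gain at these identities)
  if (length(unique(nchar(seqs))) == 1L) {
    hmin <- min(vapply(mats[-1], function(m)
      cpp_hamming_identity(mats[[1]][1, ], m[1, ]), numeric(1)))
    if (hmin >= 0.45) {
      out <- do.call(rbind, mats)
      rownames(out) <- names(seqs)
      return(out)
    }
  }
  ks <- lapply(seqs, kmer_set, k = k)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      D[i, j] <- D[j, i] <- 1 - kmer_jaccard(ks[[i]], ks[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  node <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    pick <- function(idx) if (idx < 0) mats[[-idx]] else node[[idx]]
    node[[s]] <- merge_profiles(pick(hc$merge[s, 1]), pick(hc$merge[s, 2]),
                                SM, codes, gap_open, gap_ext)
  }
  out <- node[[n - 1]]
  out[names(seqs), , drop = FALSE]
}
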