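# Distance-based tree inference with bootstrap support, rooting,
# low-support collapsing and patristic distances.  Neighbor joining is the
# desk-scale stand-in for maximum-likelihood inference: downstream decisions
# consume only topology, support and branch lengths, and an externally
# inferred Newick tree can be supplied instead.

#' Pairwise distance matrix from a concatenated alignment
#'
#' distance = 1 - identity, identity per the package-wide definition
#' (both-gap columns excluded).
#'
#' @param alignment a `concat_alignment`.
#' @param level `"protein"` or `"nucleotide"`.
#' @return symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, level = c("protein", "nucleotide")) {
  level <- match.arg(level)
  M <- if (level == "protein") alignment$aa else alignment$nt
  if (nrow(M) < 3L) stop("need >= 3 strains")
  D <- cpp_mismatch_dist(M, rep(1, ncol(M)), GAP_CODE)
  dimnames(D) <- list(rownames(M), rownames(M))
  if (anyNA(D)) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("no comparable columns for pair ", rownames(M)[bad[1]], " / ",
         rownames(M)[bad[2]])
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (additive matrices are recovered exactly);
#' negative branch lengths are clipped to zero with the total deficit stored
#' in `attr(tree, "clipped_length")`.
#'
#' @param D symmetric non-negative distance matrix with labels.
#' @return an unrooted `phylo` (stored with an arbitrary root).
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (nrow(D) < 3L) stop("need >= 3 taxa")
  tree <- ape::nj(as.dist(D))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clipped_length") <- deficit
  tree
}

#' Bootstrap support for an NJ tree
#'
#' Columns are resampled with replacement per replicate; the support of a
#' node is the percentage of replicate trees containing its bipartition.
#' The replicate trees are kept in `attr(tree, "boot_trees")` so supports can
#' be re-mapped after rooting.
#'
#' @param alignment a `concat_alignment`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param level alignment level used for distances.
#' @return the NJ tree with `node.label` supports (root NA).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 42L,
                              level = "protein") {
  stopifnot(n_replicates >= 1)
  level <- match.arg(level, c("protein", "nucleotide"))
  M <- if (level == "protein") alignment$aa else alignment$nt
  main <- neighbor_joining(distance_matrix(alignment, level))
  set.seed(seed)
  L <- ncol(M)
  boot <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    D <- cpp_mismatch_dist(M, as.numeric(w), GAP_CODE)
    dimnames(D) <- list(rownames(M), rownames(M))
    if (anyNA(D)) D[is.na(D)] <- 1
    boot[[b]] <- neighbor_joining(D)
  }
  class(boot) <- "multiPhylo"
  main <- map_support(main, boot)
  attr(main, "boot_trees") <- boot
  main
}

# assign node.label supports (%) to `tree` from a set of replicate trees,
# comparing unrooted bipartitions
map_support <- function(tree, boot) {
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  supp <- 100 * counts / length(boot)
  tree$node.label <- ifelse(is.na(supp), "", format(round(supp, 1),
                                                    trim = TRUE))
  tree
}

#' Root a tree and collapse poorly supported nodes
#'
#' Roots on the outgroup edge (or by midpoint when no outgroup is given),
#' re-maps bootstrap supports onto the rooted topology when replicate trees
#' are attached, then contracts every internal node whose support falls
#' below `support_collapse`, promoting its children (their branch lengths
#' absorb the contracted branch, so tip-to-root path lengths are preserved).
#'
#' @param tree a `phylo` with `node.label` supports (percentages).
#' @param outgroup strain ids of a monophyletic outgroup, or NULL for
#'   midpoint rooting.
#' @param support_collapse collapse threshold in percent; nodes with missing
#'   support are kept.
#' @param prune_outgroup drop the outgroup tips after rooting?
#' @return a rooted, possibly multifurcating `phylo`.
#' @export
root_and_collapse <- function(tree, outgroup = NULL, support_collapse = 50,
                              prune_outgroup = FALSE) {
  boot <- attr(tree, "boot_trees")
  if (!is.null(outgroup)) {
    miss <- setdiff(outgroup, tree$tip.label)
    if (length(miss)) stop("outgroup tip(s) not in tree: ",
                           paste(miss, collapse = ", "))
    if (!ape::is.monophyletic(tree, outgroup)) {
      stop("outgroup is not monophyletic")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
  }
  if (!is.null(boot)) tree <- map_support(tree, boot)
  tree <- collapse_low_support(tree, support_collapse)
  if (prune_outgroup && !is.null(outgroup)) {
    tree <- ape::drop.tip(tree, outgroup)
  }
  attr(tree, "boot_trees") <- NULL
  tree
}

# contract internal nodes with support < threshold (root and NA kept)
collapse_low_support <- function(tree, threshold) {
  n_tip <- length(tree$tip.label)
  root <- tree_root(tree)
  supp <- node_support(tree)
  bad_nodes <- which(!is.na(supp) & supp < threshold) + n_tip
  bad_nodes <- setdiff(bad_nodes, root)
  if (!length(bad_nodes)) return(tree)
  n_all <- n_tip + tree$Nnode
  parent <- integer(n_all)
  blen <- numeric(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  is_bad <- logical(n_all)
  is_bad[bad_nodes] <- TRUE
  final_parent <- integer(n_all)
  extra_len <- numeric(n_all)
  for (v in seq_len(n_all)) {
    if (v == root || parent[v] == 0L) next
    p <- parent[v]; add <- 0
    while (is_bad[p]) {
      add <- add + blen[p]
      p <- parent[p]
    }
    final_parent[v] <- p
    extra_len[v] <- add
  }
  keep <- c(seq_len(n_tip), setdiff((n_tip + 1L):n_all, bad_nodes))
  keep_internal <- setdiff(keep, seq_len(n_tip))
  new_id <- integer(n_all)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  new_id[sort(keep_internal)] <- n_tip + seq_along(keep_internal)
  child <- setdiff(keep, root)
  edge <- cbind(new_id[final_parent[child]], new_id[child])
  out <- list(edge = edge, tip.label = tree$tip.label,
              edge.length = blen[child] + extra_len[child],
              Nnode = length(keep_internal))
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[sort(keep_internal) - n_tip]
  }
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the unique path between `a` and `b`.  Computed
#' on the tree as given; use the uncollapsed tree (collapsing discards
#' branch-length information into its children).
#'
#' @param tree a `phylo`.
#' @param a,b tip labels.
#' @export
patristic_distance <- function(tree, a, b) {
  miss <- setdiff(c(a, b), tree$tip.label)
  if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "))
  if (a == b) return(0)
  pd <- patristic_matrix(tree)
  pd[a, b]
}

#' All-pairs patristic distance matrix
#' @rdname patristic_distance
#' @export
patristic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}
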