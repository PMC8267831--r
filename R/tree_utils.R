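# Small rooted-tree helpers shared by the generator, phyly and the decision
# engine.  Trees are ape "phylo" objects; tips are strain ids.

# list of descendant tip-label sets, indexed by node number (tips included)
tree_tipsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

tree_root <- function(tree) {
  n_tip <- length(tree$tip.label)
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

# children of each node
tree_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(length(tree$tip.label) +
                                                  tree$Nnode)))
}

# node depths (sum of branch lengths root -> node)
node_depths <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  d <- numeric(n_all)
  pr <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edges
  for (e in rev(seq_len(nrow(pr$edge)))) {
    d[pr$edge[e, 2]] <- d[pr$edge[e, 1]] + pr$edge.length[e]
  }
  d
}

# heights above the tips for an ultrametric tree
node_heights <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(length(tree$tip.label))]) - d
}

# MRCA that also works for single-tip groups
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip(s): ", paste(tips[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, tips)
}

# single-tip phylo used to graft one tip onto a tree
single_tip_phylo <- function(label, length = 0) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = length, Nnode = 1L),
            class = "phylo")
}
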