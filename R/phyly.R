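# Mono-/para-/polyphyly classification of label groups on a rooted tree.
#
# Operational rule (stated prominently since other conventions exist): the
# intruders are the non-group tips under the group's MRCA; the group is
# monophyletic when there are none, paraphyletic when the intruder set is
# itself monophyletic (its own MRCA contains no group tips), and
# polyphyletic otherwise.  Classification is normally run on the collapsed
# tree, so only well-supported structure separates groups.

#' Classify a tip group as mono-, para- or polyphyletic
#'
#' @param tree a rooted `phylo`.
#' @param group character vector of tip labels.
#' @return a `phyly_report`: group tips, `status`, `mrca_tips`, `intruders`
#'   and `pure_clades` (maximal subtrees containing only group tips, ordered
#'   by first appearance in the tree).
#' @export
classify_group <- function(tree, group) {
  if (!length(group)) stop("empty group")
  # the tree is treated as rooted at its stored root; collapsed trees may
  # carry a root polytomy, which ape::is.rooted would reject
  miss <- setdiff(group, tree$tip.label)
  if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "))
  tipsets <- tree_tipsets(tree)
  mrca <- mrca_node(tree, group)
  mrca_tips <- tipsets[[mrca]]
  intruders <- setdiff(mrca_tips, group)
  status <- if (!length(intruders)) {
    "monophyletic"
  } else {
    i_mrca <- mrca_node(tree, intruders)
    if (!length(intersect(tipsets[[i_mrca]], group))) "paraphyletic"
    else "polyphyletic"
  }
  # maximal pure clades: nodes (or tips) whose tip set is inside the group
  # while the parent's is not
  n_all <- length(tree$tip.label) + tree$Nnode
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pure <- vapply(seq_len(n_all), function(v) {
    all(tipsets[[v]] %in% group)
  }, logical(1))
  maximal <- which(pure & (parent == 0L | !pure[pmax(parent, 1L)]))
  ord <- order(vapply(maximal, function(v) min(match(tipsets[[v]],
                                                     tree$tip.label)),
                      integer(1)))
  pure_clades <- lapply(maximal[ord], function(v) tipsets[[v]])
  structure(list(group = group, status = status, mrca_tips = mrca_tips,
                 intruders = intruders, pure_clades = pure_clades),
            class = "phyly_report")
}

#' @export
print.phyly_report <- function(x, ...) {
  cat("<phyly_report>", x$status, "-", length(x$group), "tips,",
      length(x$intruders), "intruders,", length(x$pure_clades),
      "pure clade(s)\n")
  invisible(x)
}

#' Index of the pure clade containing the type species
#'
#' The "primary clade" of a split genus retains the genus name.
#' @param report a `phyly_report`.
#' @param type_species_tip tip label of the genus' type species.
#' @return 1-based index into `report$pure_clades`.
#' @export
find_primary_clade <- function(report, type_species_tip) {
  if (is.null(type_species_tip) || is.na(type_species_tip) ||
      !type_species_tip %in% report$group) {
    stop("type species tip is not part of the group")
  }
  idx <- which(vapply(report$pure_clades,
                      function(tp) type_species_tip %in% tp, logical(1)))
  if (!length(idx)) stop("type species not in any pure clade")
  idx[1]
}

#' Find the two major lineages of a rooted tree
#'
#' The two largest disjoint clades, each with support at least
#' `support_min`, jointly covering at least `coverage_min` of the tips.
#' Tips outside both (basal monospecific strains) are returned unassigned.
#'
#' @param tree rooted `phylo` with `node.label` supports; nodes with missing
#'   support qualify.
#' @param support_min minimum bootstrap support (percent).
#' @param coverage_min minimum joint tip coverage fraction.
#' @return list with tip sets `a`, `b` and `unassigned`.
#' @export
two_major_lineages <- function(tree, support_min = 95, coverage_min = 0.9) {
  n_tip <- length(tree$tip.label)
  tipsets <- tree_tipsets(tree)
  supp <- node_support(tree)
  root <- tree_root(tree)
  cand <- setdiff(which(is.na(supp) | supp >= support_min) + n_tip, root)
  cand <- c(cand, seq_len(n_tip))
  ord <- cand[order(-lengths(tipsets)[cand])]
  best <- NULL; best_cov <- -1
  for (ii in seq_along(ord)) {
    t1 <- tipsets[[ord[ii]]]
    if ((length(t1) + length(t1)) / n_tip < best_cov) break
    for (jj in seq_along(ord)[-seq_len(ii)]) {
      t2 <- tipsets[[ord[jj]]]
      if (length(intersect(t1, t2))) next
      cov <- (length(t1) + length(t2)) / n_tip
      # candidates are size-ordered: the first disjoint partner is the best
      # partner for t1
      if (cov > best_cov) { best <- list(a = t1, b = t2); best_cov <- cov }
      break
    }
  }
  if (is.null(best) || best_cov < coverage_min) {
    stop("no pair of well-supported disjoint clades covers ",
         coverage_min * 100,
         "% of tips; assign lineages manually")
  }
  list(a = best$a, b = best$b,
       unassigned = setdiff(tree$tip.label, c(best$a, best$b)))
}
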