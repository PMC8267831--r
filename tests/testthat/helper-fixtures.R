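# Shared fixtures, built in code.  Small simulations are memoised per test
# session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

# a small clean dataset (16 tips, 12 genes)
small_sim <- function() {
  memo_fixture("small_sim", function() {
    simulate_dataset(simulation_config(n_tips = 16, n_genes = 12,
                                       gene_length_codons = 150,
                                       seed = 7L))
  })
}

# a hand-built strain record with controllable marker content
toy_record <- function(id = "s1", markers = character(),
                       marker_copies = rep(1L, length(markers)),
                       n_core = 5L, nacl = NA_real_, genus = "gA",
                       species = paste0(id, "_sp"), type = FALSE,
                       year = 1950L, family = NA_character_,
                       seed = 1L) {
  set.seed(seed)
  core_markers <- sprintf("qcm%02d", seq_len(n_core))
  labels <- c(core_markers, rep(markers, marker_copies))
  nts <- vapply(seq_along(labels), function(i) {
    paste0("ATG", paste(sample(c("GCT", "GGT", "TGT", "CAT", "AAA", "CTG"),
                               29, replace = TRUE), collapse = ""))
  }, character(1))
  prots <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nts)))
  genes <- gene_table(paste0(id, "_g", seq_along(labels)), nts, prots,
                      labels)
  strain_record(id, setNames(paste(nts, collapse = ""), id), genes,
                genus = genus, species = species, is_type_species = type,
                genus_year = year, nacl_percent = nacl, family = family)
}

# random rooted binary tree with branch lengths, as phylo
random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("x%02d", seq_len(n))
  tr
}

# --- independent brute-force oracles ----------------------------------------

# all clades (tip-label sets) of a rooted tree, computed without the package
oracle_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  edges <- tree$edge[order(-tree$edge[, 2]), , drop = FALSE]
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      if (is.null(sets[[p]])) sets[[p]] <- character()
      if (!is.null(sets[[ch]]) && !all(sets[[ch]] %in% sets[[p]])) {
        sets[[p]] <- union(sets[[p]], sets[[ch]])
        done <- FALSE
      }
    }
    if (done) break
  }
  sets
}

# definition-based phyly classification: monophyletic iff the group equals
# some clade; else paraphyletic iff the intruders within the smallest
# containing clade themselves equal a clade (or a single tip); else
# polyphyletic
oracle_phyly <- function(tree, group) {
  clades <- oracle_clades(tree)
  is_clade <- function(s) {
    length(s) == 1L ||
      any(vapply(clades, function(cl) setequal(cl, s), logical(1)))
  }
  if (is_clade(group)) return("monophyletic")
  sizes <- vapply(clades, length, integer(1))
  containing <- which(vapply(clades, function(cl) all(group %in% cl),
                             logical(1)))
  smallest <- containing[which.min(sizes[containing])]
  intruders <- setdiff(clades[[smallest]], group)
  if (is_clade(intruders)) "paraphyletic" else "polyphyletic"
}

# brute-force patristic distance: sum branch lengths along root paths
oracle_patristic <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  blen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v; out <- integer()
    while (parent[p] != 0L) { out <- c(out, p); p <- parent[p] }
    out
  }
  va <- match(a, tree$tip.label); vb <- match(b, tree$tip.label)
  pa <- path_to_root(va); pb <- path_to_root(vb)
  shared <- intersect(pa, pb)
  sum(blen[setdiff(pa, shared)]) + sum(blen[setdiff(pb, shared)])
}

# enumerate all rooted binary topologies over the given tip labels as
# Newick strings
enumerate_rooted_trees <- function(tips) {
  n <- length(tips)
  if (n == 1L) return(tips)
  rest <- tips[-1]
  out <- character()
  # the left child keeps tips[1] (canonical orientation); every strict
  # subset of the remaining tips may join it
  for (s in 0:(2^(n - 1) - 2)) {
    sel <- as.logical(bitwAnd(s, 2^(seq_len(n - 1) - 1)))
    left <- c(tips[1], rest[sel]); right <- rest[!sel]
    for (lt in enumerate_rooted_trees(left)) {
      for (rt in enumerate_rooted_trees(right)) {
        out <- c(out, paste0("(", lt, ",", rt, ")"))
      }
    }
  }
  out
}
# memoised analysis context over the small clean dataset
small_ctx <- function() {
  memo_fixture("small_ctx", function() {
    build_analysis_context(small_sim()$records, n_boot = 25, seed = 7)
  })
}

# small dataset with one basal monospecific graft (a long isolated branch)
basal_sim <- function() {
  memo_fixture("basal_sim", function() {
    simulate_dataset(simulation_config(n_tips = 16, n_genes = 12,
                                       gene_length_codons = 150,
                                       seed = 9L, n_basal = 1L))
  })
}
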