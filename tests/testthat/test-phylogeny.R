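test_that("distance_matrix counts mismatches per the identity definition", {
  aa <- rbind(a = seq_to_int("MKLVNN"), b = seq_to_int("MKLVNN"),
              c = seq_to_int("MKLANN"))
  al <- structure(list(aa = aa, nt = aa, strains = rownames(aa),
                       blocks = data.frame()), class = "concat_alignment")
  D <- distance_matrix(al, "protein")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / 6)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), rownames(aa)))
})

test_that("NJ solves the 3-taxon case in closed form", {
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.2)
  expect_equal(bl[["C"]], 0.3)
})

test_that("NJ recovers additive matrices exactly", {
  for (seed in 1:10) {
    tr <- random_rooted_tree(8, seed)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj))[1], 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ on ultrametric matrices matches the UPGMA topology", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rcoal(7)
    tr$tip.label <- paste0("u", 1:7)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    up <- ape::as.phylo(stats::hclust(as.dist(D), "average"))
    expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(up))[1], 0)
  }
})

test_that("bootstrap saturates on repeated signal and is deterministic", {
  sim <- small_sim()
  core <- build_core_alignment(sim$records)
  sub <- list(aa = core$alignment$aa[1:8, ], nt = core$alignment$nt[1:8, ],
              strains = core$alignment$strains[1:8],
              blocks = core$alignment$blocks)
  class(sub) <- "concat_alignment"
  t1 <- bootstrap_support(sub, n_replicates = 30, seed = 5)
  supp <- node_support(t1)
  expect_true(all(supp[!is.na(supp)] >= 95)) # overwhelming columns
  t2 <- bootstrap_support(sub, n_replicates = 30, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
})

test_that("root_and_collapse contracts low-support nodes and keeps paths", {
  tr <- read_newick("(((A:1,B:1)40:1,C:2)90:1,(D:1,E:1)80:2)root;")
  col <- collapse_low_support(tr, 50)
  # AB node gone -> polytomy A,B,C
  expect_equal(col$Nnode, tr$Nnode - 1L)
  rep <- classify_group(col, c("A", "B"))
  # A,B now sit in a polytomy with C: no longer a clade of their own
  expect_identical(rep$status, "paraphyletic")
  pd0 <- patristic_matrix(tr); pd1 <- patristic_matrix(col)
  expect_equal(pd1["A", "D"], pd0["A", "D"], tolerance = 1e-9)
  expect_equal(pd1["A", "C"], pd0["A", "C"], tolerance = 1e-9)
  # idempotent
  col2 <- collapse_low_support(col, 50)
  expect_equal(col2$edge, col$edge)
  # all supports above threshold: unchanged topology
  keep <- collapse_low_support(tr, 30)
  expect_equal(keep$Nnode, tr$Nnode)
})

test_that("rooting validates the outgroup", {
  tr <- read_newick("(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  expect_error(root_and_collapse(tr, outgroup = c("A", "D")),
               "not monophyletic")
  expect_error(root_and_collapse(tr, outgroup = c("Z")), "not in tree")
  rooted <- root_and_collapse(tr, outgroup = c("D", "E"),
                              prune_outgroup = TRUE)
  expect_setequal(rooted$tip.label, c("A", "B", "C"))
})

test_that("patristic distances match brute-force path enumeration", {
  tr <- read_newick("((A:0.1,B:0.2):0.5,C:1);")
  expect_equal(patristic_distance(tr, "A", "B"), 0.3)
  expect_equal(patristic_distance(tr, "A", "A"), 0)
  expect_error(patristic_distance(tr, "A", "Z"), "unknown tip")
  for (seed in 11:15) {
    tr <- random_rooted_tree(10, seed)
    pd <- patristic_matrix(tr)
    pick <- combn(tr$tip.label, 2)[, sample(45, 10)]
    for (k in seq_len(ncol(pick))) {
      expect_equal(pd[pick[1, k], pick[2, k]],
                   oracle_patristic(tr, pick[1, k], pick[2, k]),
                   tolerance = 1e-9)
    }
  }
})

test_that("patristic matrices satisfy the four-point condition", {
  for (seed in 21:23) {
    tr <- random_rooted_tree(8, seed)
    pd <- patristic_matrix(tr)
    q <- combn(tr$tip.label, 4)[, sample(70, 15)]
    for (k in seq_len(ncol(q))) {
      s <- q[, k]
      sums <- c(pd[s[1], s[2]] + pd[s[3], s[4]],
                pd[s[1], s[3]] + pd[s[2], s[4]],
                pd[s[1], s[4]] + pd[s[2], s[3]])
      two_max <- sort(sums, decreasing = TRUE)[1:2]
      expect_lt(abs(two_max[1] - two_max[2]), 1e-9)
    }
  }
})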