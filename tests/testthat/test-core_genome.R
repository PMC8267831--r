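mk_gene_rec <- function(id, prot_list, genus = "gA") {
  nts <- vapply(prot_list, function(p) {
    # reverse-translate with a fixed codon per amino acid
    codons <- c(M = "ATG", A = "GCT", C = "TGT", D = "GAT", E = "GAA",
                F = "TTT", G = "GGT", H = "CAT", I = "ATT", K = "AAA",
                L = "CTG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
    paste(codons[strsplit(p, "")[[1]]], collapse = "")
  }, character(1))
  genes <- gene_table(paste0(id, "_g", seq_along(prot_list)), nts,
                      unlist(prot_list))
  strain_record(id, setNames(paste(nts, collapse = ""), id), genes,
                genus = genus, species = paste0(id, "_sp"))
}

test_that("greedy clustering applies the core and single-copy rules", {
  p <- "MKKLVAADEGHTWYSRNPQC"
  ds <- as_dataset(list(mk_gene_rec("s1", list(p)), mk_gene_rec("s2", list(p)),
                        mk_gene_rec("s3", list(p))))
  cl <- cluster_genes(ds, 0.5)
  expect_length(cl, 1)
  expect_true(cl[[1]]$is_core)

  # present in only 2 of 3 genomes -> not core
  other <- "MYYTTRRSSGGHHEEDDCCA"
  ds2 <- as_dataset(list(mk_gene_rec("s1", list(p, other)),
                         mk_gene_rec("s2", list(p, other)),
                         mk_gene_rec("s3", list(p))))
  cl2 <- cluster_genes(ds2, 0.5)
  expect_length(cl2, 2)
  core_flags <- vapply(cl2, function(x) x$is_core, logical(1))
  expect_equal(sum(core_flags), 1)

  # a within-strain paralog pair makes the cluster multi-copy -> not core
  paralog <- sub("C$", "A", p)
  ds3 <- as_dataset(list(mk_gene_rec("s1", list(p, paralog)),
                         mk_gene_rec("s2", list(p)),
                         mk_gene_rec("s3", list(p))))
  cl3 <- cluster_genes(ds3, 0.5)
  expect_length(cl3, 1)
  expect_false(cl3[[1]]$is_core)

  expect_error(cluster_genes(ds, 0), "identity_threshold")
  expect_error(cluster_genes(ds, 1.2), "identity_threshold")
})

test_that("clustering partitions the input genes", {
  sim <- small_sim()
  cl <- cluster_genes(sim$records, 0.5)
  all_members <- do.call(rbind, lapply(cl, function(x)
    x$members[, c("strain_id", "gene_id")]))
  n_in <- sum(vapply(sim$records, function(r)
    sum(!is.na(r$genes$protein_seq)), integer(1)))
  expect_equal(nrow(all_members), n_in)
  expect_false(anyDuplicated(paste(all_members$strain_id,
                                   all_members$gene_id)) > 0)
})

test_that("with no accessory loss the generator's gene count is recovered", {
  cfg <- simulation_config(n_tips = 10, n_genes = 15,
                           gene_length_codons = 120,
                           accessory_gene_prob = 0, seed = 31)
  tax <- simulate_taxonomy_tree(cfg)
  rec <- evolve_genomes(tax$tree, cfg, tax$taxonomy)
  cl <- cluster_genes(rec, 0.5)
  expect_equal(sum(vapply(cl, function(x) x$is_core, logical(1))), 15)
})

test_that("align_cluster produces faithful codon-aware blocks", {
  p <- "MKKLVAADEGHTWYSRNPQC"
  ds <- as_dataset(list(mk_gene_rec("s1", list(p)),
                        mk_gene_rec("s2", list(p))))
  cl <- cluster_genes(ds, 0.5)
  b <- align_cluster(cl[[1]])
  expect_equal(ncol(b$aa), nchar(p))      # identical -> zero gaps
  expect_false(any(b$aa == GAP_CODE))
  expect_equal(ncol(b$nt), 3 * ncol(b$aa))

  # one internal single-residue deletion -> exactly one gap column
  pdel <- paste0(substr(p, 1, 9), substr(p, 11, nchar(p)))
  ds2 <- as_dataset(list(mk_gene_rec("s1", list(p)),
                         mk_gene_rec("s2", list(pdel))))
  cl2 <- cluster_genes(ds2, 0.5)
  b2 <- align_cluster(cl2[[1]])
  expect_equal(ncol(b2$aa), nchar(p))
  expect_equal(sum(b2$aa == GAP_CODE), 1)
  # back-translation: residue columns triple, gaps become triple gaps
  expect_equal(sum(b2$nt == GAP_CODE), 3)
  # alignment never reorders residues (subsequence property)
  for (i in 1:2) {
    row <- b2$aa[i, ]
    expect_identical(intToUtf8(row[row != GAP_CODE]),
                     c(p, pdel)[i])
  }
  expect_error(align_cluster(list(is_core = FALSE)), "core")
})

test_that("concatenate checks strain sets and records partitions", {
  p1 <- "MKKLVAADEGHTWYSRNPQC"
  p2 <- "MYYTTRRSSGGHHEEDDCCA"
  ds <- as_dataset(list(mk_gene_rec("s1", list(p1, p2)),
                        mk_gene_rec("s2", list(p1, p2))))
  cl <- cluster_genes(ds, 0.5)
  blocks <- lapply(cl, align_cluster)
  al <- concatenate(blocks)
  expect_equal(ncol(al$aa), nchar(p1) + nchar(p2))
  expect_equal(ncol(al$nt), 3 * ncol(al$aa))
  expect_equal(nrow(al$blocks), 2)
  expect_equal(al$blocks$aa_start[2], nchar(p1) + 1)
  expect_error(concatenate(list()), "empty")
  b_bad <- blocks
  b_bad[[2]]$aa <- b_bad[[2]]$aa["s1", , drop = FALSE]
  expect_error(concatenate(b_bad), "strain sets differ")
})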