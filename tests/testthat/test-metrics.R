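# helper: mutate exactly a fraction of sites of a genome string to a
# different base (deterministic divergence, unlike the Poisson engine)
mutate_fraction <- function(seq, frac, seed) {
  set.seed(seed)
  x <- seq_to_int(seq)
  n <- round(frac * length(x))
  sites <- sample(length(x), n)
  alt <- vapply(x[sites], function(b) {
    sample(setdiff(c(65L, 67L, 71L, 84L), b), 1)
  }, integer(1))
  x[sites] <- alt
  int_to_seq(x)
}

plain_genome_rec <- function(id, seq) {
  genes <- gene_table(paste0(id, "_g1"), substr(seq, 1, 300),
                      as.character(Biostrings::translate(
                        Biostrings::DNAStringSet(substr(seq, 1, 300)))))
  strain_record(id, setNames(seq, id), genes, genus = "g", species = id)
}

test_that("gc_content counts bases and excludes ambiguity codes", {
  expect_equal(gc_content(plain_genome_rec("a", strrep("GGCC", 100))), 100)
  expect_equal(gc_content(plain_genome_rec("b", strrep("ATGC", 100))), 50)
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  counts <- table(strsplit(s, "")[[1]])
  want <- 100 * (counts[["G"]] + counts[["C"]]) / sum(counts)
  expect_equal(gc_content(plain_genome_rec("c", s)), want)
  # ambiguity codes drop out of numerator and denominator
  r <- plain_genome_rec("d", paste0(strrep("ATGC", 100), strrep("N", 50)))
  expect_equal(gc_content(r), 50)
})

test_that("identical genomes give ANI, AAI and dDDH of exactly 100", {
  sim <- small_sim()
  a <- sim$records[[1]]
  b <- a; b$strain_id <- "copy"
  m <- ani_dddh(a, b)
  expect_identical(m$ani, 100)
  expect_identical(m$dddh, 100)
  expect_identical(aai(a, b), 100)
})

test_that("ANI tracks a constructed mutation load (5% -> 95 +- 0.5)", {
  set.seed(72)
  g <- paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
             collapse = "")
  a <- plain_genome_rec("a", g)
  b <- plain_genome_rec("b", mutate_fraction(g, 0.05, seed = 73))
  got <- ani(a, b)
  expect_lt(abs(got - 95), 0.5)
})

test_that("dDDH decreases strictly with mutation load", {
  set.seed(74)
  g <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
             collapse = "")
  a <- plain_genome_rec("a", g)
  vals <- vapply(c(0.01, 0.02, 0.05, 0.10), function(f) {
    ddd_hybridization(a, plain_genome_rec("b", mutate_fraction(g, f, 75)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 70) # 10% load is far past the species boundary
})

test_that("AAI tracks proteome substitution (10% -> ~90 +- 1)", {
  set.seed(76)
  nts <- vapply(1:25, function(i) random_cds(150), character(1))
  prots <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nts)))
  mk <- function(id, pr) {
    genes <- gene_table(paste0(id, "_g", seq_along(pr)), nts, pr)
    strain_record(id, setNames(paste(nts, collapse = ""), id), genes,
                  genus = "g", species = id)
  }
  a <- mk("a", prots)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  prots_b <- vapply(prots, function(p) {
    ch <- strsplit(p, "")[[1]]
    sites <- sample(length(ch), round(0.1 * length(ch)))
    ch[sites] <- vapply(ch[sites], function(x)
      sample(setdiff(aa20, x), 1), character(1))
    paste(ch, collapse = "")
  }, character(1))
  b <- mk("b", unname(prots_b))
  b$genes$codon_ok <- TRUE # proteins intentionally decoupled from CDS here
  got <- aai(a, b)
  expect_lt(abs(got - 90), 1)
})

test_that("metrics are symmetric in the pair", {
  sim <- small_sim()
  ids <- names(sim$records)[1:4]
  cache <- new_metric_cache()
  for (k in 2:4) {
    a <- sim$records[[ids[1]]]; b <- sim$records[[ids[k]]]
    m1 <- ani_dddh(a, b, cache = cache)
    m2 <- ani_dddh(b, a, cache = cache)
    expect_equal(m1$ani, m2$ani, tolerance = 1e-9)
    expect_equal(m1$dddh, m2$dddh, tolerance = 1e-9)
    expect_equal(aai(a, b, cache = cache), aai(b, a, cache = cache),
                 tolerance = 1e-9)
  }
})

test_that("ANI rank order follows true tree path lengths", {
  # genomes large enough that fragment sampling noise stays well below the
  # identity differences between neighboring divergence levels
  sim <- simulate_dataset(simulation_config(n_tips = 16, n_genes = 40,
                                            gene_length_codons = 200,
                                            seed = 7))
  pd <- ape::cophenetic.phylo(sim$truth$tree)
  cache <- new_metric_cache()
  set.seed(77)
  pairs <- t(combn(names(sim$records), 2))
  pairs <- pairs[sample(nrow(pairs), 30), , drop = FALSE]
  anis <- vapply(seq_len(nrow(pairs)), function(r) {
    ani(sim$records[[pairs[r, 1]]], sim$records[[pairs[r, 2]]],
        cache = cache)
  }, numeric(1))
  paths <- pd[pairs]
  rho <- stats::cor(anis, -paths, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("codon-position similarity counts per-position columns", {
  nt <- rbind(a = seq_to_int("ATGGCTTGTAAA"), b = seq_to_int("ATGGCTTGTAAA"))
  al <- structure(list(aa = nt, nt = nt, strains = c("a", "b"),
                       blocks = data.frame()), class = "concat_alignment")
  expect_equal(unname(codon_position_similarity(al, "a", "b")),
               c(100, 100, 100))
  # mutate position 3 of half the codons of one row
  ntb <- seq_to_int("ATGGCTTGTAAA")
  ntb[c(6, 12)] <- seq_to_int("GG") # codons 2 and 4, position 3
  al2 <- al
  al2$nt <- rbind(a = nt["a", ], b = ntb)
  got <- codon_position_similarity(al2, "a", "b")
  expect_equal(unname(got), c(100, 100, 50))
})

test_that("cp3 diverges fastest under the elevated third-position rate", {
  sim <- small_sim()
  core <- build_core_alignment(sim$records)
  cp <- cp_similarity_matrices(core$alignment)
  ids <- core$alignment$strains
  off <- upper.tri(cp$cp1)
  expect_gt(mean(cp$cp1[off]), mean(cp$cp3[off]))
  expect_gt(mean(cp$cp2[off]), mean(cp$cp3[off]))
})

test_that("16S identity uses the marker gene and flags its absence", {
  sim <- small_sim()
  a <- sim$records[[1]]; b <- sim$records[[2]]
  got <- s16_identity(a, b)
  s16 <- function(r) r$genes$nucleotide_seq[r$genes$marker_label == "16S"]
  expect_equal(got, 100 * mean(seq_to_int(s16(a)) == seq_to_int(s16(b))),
               tolerance = 1e-6)
  expect_identical(s16_identity(a, a), 100)
  c <- b
  c$genes <- c$genes[c$genes$marker_label != "16S", , drop = FALSE]
  expect_warning(res <- s16_identity(a, c), "missing 16S")
  expect_true(is.na(res))
})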