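test_that("taxonomy simulation is clean, labelled and deterministic", {
  cfg <- simulation_config(n_tips = 20, n_genes = 8,
                           gene_length_codons = 60, seed = 3)
  tax <- simulate_taxonomy_tree(cfg)
  expect_equal(length(tax$tree$tip.label), 20)
  expect_gte(length(unique(tax$taxonomy$genus)), 2)
  # every genus monophyletic in truth, every genus has one type species
  for (g in unique(tax$taxonomy$genus)) {
    tips <- tax$taxonomy$strain_id[tax$taxonomy$genus == g]
    expect_identical(classify_group(tax$tree, tips)$status, "monophyletic")
    expect_equal(sum(tax$taxonomy$is_type_species[
      tax$taxonomy$genus == g]), 1)
  }
  # distinct genus years back the priority rule
  yr <- unique(tax$taxonomy[, c("genus", "genus_year")])
  expect_false(anyDuplicated(yr$genus_year) > 0)
  # determinism
  tax2 <- simulate_taxonomy_tree(cfg)
  expect_identical(write_newick(tax$tree), write_newick(tax2$tree))
  expect_identical(tax$taxonomy, tax2$taxonomy)
  # a cutoff too generous for genus structure errors out
  expect_error(simulate_taxonomy_tree(
    simulation_config(n_tips = 8, genus_depth = 50, seed = 3)),
    "smaller cutoff")
})

test_that("pre-injection genera stay monophyletic across replicates", {
  for (seed in 51:56) {
    cfg <- simulation_config(n_tips = 30, seed = seed)
    tax <- simulate_taxonomy_tree(cfg)
    for (g in unique(tax$taxonomy$genus)) {
      tips <- tax$taxonomy$strain_id[tax$taxonomy$genus == g]
      expect_identical(classify_group(tax$tree, tips)$status,
                       "monophyletic")
    }
  }
})

test_that("the substitution engine follows the Jukes-Cantor expectation", {
  set.seed(99)
  L <- 60000L
  x0 <- sample(c(65L, 67L, 71L, 84L), L, replace = TRUE)
  d <- 0.025
  x1 <- mutate_seq_int(x0, d)
  x2 <- mutate_seq_int(x0, d)
  # pair at total path 2d = 0.05: identity ~ 1/4 + 3/4 exp(-4/3 * 0.05)
  p_match <- 1 / 4 + 3 / 4 * exp(-4 / 3 * 2 * d)
  obs <- mean(x1 == x2)
  sigma <- sqrt(p_match * (1 - p_match) / L)
  expect_lt(abs(obs - p_match), 3 * sigma)
  # zero rate: identical
  expect_identical(mutate_seq_int(x0, 0), x0)
})

test_that("coding evolution respects codon-position rates and avoids stops", {
  set.seed(100)
  cds <- random_cds(20000L)
  x0 <- seq_to_int(cds)
  w <- c(0.5, 0.4, 2.1)
  x1 <- mutate_seq_int(x0, 0.1, coding = TRUE, pos_w = w)
  s <- seq.int(1L, length(x1), 3L)
  expect_false(any(is_stop_codon(x1[s], x1[s + 1], x1[s + 2])))
  # per-position divergence tracks the multipliers
  div <- vapply(1:3, function(k) {
    idx <- seq.int(k, length(x0), 3L)
    mean(x0[idx] != x1[idx])
  }, numeric(1))
  expect_gt(div[3], 2.5 * div[2])
  expect_gt(div[3], 2 * div[1])
})

test_that("zero mutation rate gives identical genomes and ANI 100", {
  cfg <- simulation_config(n_tips = 6, n_genes = 6,
                           gene_length_codons = 100,
                           site_mutation_rate = 0, accessory_gene_prob = 0,
                           seed = 13)
  tax <- simulate_taxonomy_tree(cfg)
  rec <- evolve_genomes(tax$tree, cfg, tax$taxonomy)
  g1 <- genome_string(rec[[1]])
  for (r in rec[-1]) expect_identical(genome_string(r), g1)
  m <- ani_dddh(rec[[1]], rec[[2]])
  expect_equal(m$ani, 100)
  expect_equal(m$dddh, 100)
})

test_that("trait draws follow the family-conditional probabilities", {
  # records fresh from the evolver, before any markers were inserted
  cfg <- simulation_config(n_tips = 8, n_genes = 6,
                           gene_length_codons = 60, seed = 37)
  tax <- simulate_taxonomy_tree(cfg)
  rec <- evolve_genomes(tax$tree, cfg, tax$taxonomy)
  ones <- default_trait_probs()
  ones[, -1] <- 1
  tr1 <- draw_traits(rec, ones, seed = 2)
  expect_true(all(as.matrix(tr1$traits[, -(1:2)])))
  prof <- trait_profiles(tr1$records)
  expect_true(all(prof$dmsp_demethylation & prof$dmsp_cleavage &
                    prof$ahl_qs))
  zeros <- default_trait_probs()
  zeros[, -1] <- 0
  tr0 <- draw_traits(rec, zeros, seed = 2)
  prof0 <- trait_profiles(tr0$records)
  expect_false(any(prof0$dmsp_demethylation | prof0$dmsp_cleavage |
                     prof0$ahl_qs))
  # missing family row errors
  bad <- default_trait_probs()[1, , drop = FALSE]
  expect_error(draw_traits(rec, bad, seed = 2), "missing family row")
})

test_that("trait frequencies recover the configured probability", {
  # famA cleavage prob 0.6 at n = 500: within 3 sigma of binomial
  set.seed(17)
  n <- 500L
  recs <- lapply(seq_len(n), function(i) {
    toy_record(sprintf("r%03d", i), family = "famA", seed = i)
  })
  recs <- as_dataset(recs)
  probs <- default_trait_probs()
  probs$dmsp_cleavage <- c(0.6, 0.6)
  tr <- draw_traits(recs, probs, seed = 23)
  p_hat <- mean(tr$traits$dmsp_cleavage)
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("fixed seeds give byte-identical dataset directories", {
  cfg <- simulation_config(n_tips = 10, n_genes = 8,
                           gene_length_codons = 80, seed = 29,
                           injections = list(n_para = 1, n_split = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- suppressWarnings(simulate_dataset(cfg))
  write_dataset(s1$records, d1, truth = s1$truth)
  s2 <- suppressWarnings(simulate_dataset(cfg))
  write_dataset(s2$records, d2, truth = s2$truth)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("injections relabel as announced and ledger them exactly once", {
  cfg <- simulation_config(n_tips = 40, n_genes = 10,
                           gene_length_codons = 80, seed = 21,
                           injections = list(n_para = 1, n_poly = 1,
                                             n_split = 1))
  sim <- suppressWarnings(simulate_dataset(cfg))
  led <- sim$truth$ledger
  expect_equal(nrow(led), length(unique(led$event_id)))
  claimed_genus <- vapply(sim$records, function(r) r$genus, character(1))
  # paraphyly: the claimed genus of the moved tip differs from truth and is
  # reported paraphyletic on the truth tree under claimed labels
  para <- led[led$kind == "paraphyly", ]
  if (nrow(para)) {
    x <- para$expected_subjects
    expect_identical(unname(claimed_genus[x]), para$target)
    tips_y <- names(claimed_genus)[claimed_genus == para$target]
    expect_identical(classify_group(sim$tree, tips_y)$status,
                     "paraphyletic")
  }
  poly <- led[led$kind == "polyphyly", ]
  if (nrow(poly)) {
    tips_x <- names(claimed_genus)[claimed_genus == poly$target]
    expect_identical(classify_group(sim$tree, tips_x)$status,
                     "polyphyletic")
  }
  split <- led[led$kind == "species_split", ]
  if (nrow(split)) {
    pair <- strsplit(split$expected_subjects, ";")[[1]]
    m <- ani_dddh(sim$records[[pair[1]]], sim$records[[pair[2]]])
    expect_gte(m$ani, 95)
    expect_gte(m$dddh, 70)
  }
  # colliding events are rejected
  ev <- list(list(kind = "paraphyly", target = "gX",
                  detail = list(tip = names(sim$records)[1],
                                from_genus = claimed_genus[[1]])),
             list(kind = "species_split", target = names(sim$records)[1],
                  detail = list(new_tip = "zz")))
  ev[[2]]$target <- names(claimed_genus)[claimed_genus ==
                                           claimed_genus[[1]]][1]
  expect_error(
    inject_misclassifications(sim$records, sim$tree, list(
      list(kind = "species_split", target = ev[[2]]$target,
           detail = list(new_tip = "zz")),
      list(kind = "species_split", target = ev[[2]]$target,
           detail = list(new_tip = "zz2")))),
    "collides")
})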